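# Voxelwise two-sample GLM with nuisance covariates, TFCE, and permutation
# family-wise error correction (max-statistic distribution), mirroring the
# standard nonparametric inference used for lesion and disconnection maps.

#' Build a two-group design matrix with nuisance covariates
#'
#' Encodes the model `y ~ intercept + group + covariates` fitted at every
#' voxel. The group indicator is 1 for the first level (so positive t means
#' group 1 > group 2); covariates (typically lesion volume) are mean-centered.
#'
#' @param group factor or character vector of group labels (exactly 2 levels,
#'   both present). The first level (factor order, or order of appearance) is
#'   coded 1.
#' @param covariates optional numeric vector or matrix of per-subject
#'   nuisance covariates, e.g. lesion volume in mm^3.
#' @return object of class `design_matrix` with fields `X` (n x p), `contrast`
#'   (length p), `group` (the indicator), `levels`, `n`.
#' @export
design_matrix <- function(group, covariates = NULL) {
  if (!is.factor(group)) group <- factor(group, levels = unique(group))
  if (nlevels(group) != 2L || any(table(group) == 0L))
    stop("`group` must have exactly two levels, both present")
  g <- as.integer(group == levels(group)[1])
  X <- cbind(intercept = 1, group = g)
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    if (nrow(C) != length(g)) stop("covariate rows must match subjects")
    C <- scale(C, center = TRUE, scale = FALSE)
    colnames(C) <- if (is.null(colnames(C)))
      paste0("cov", seq_len(ncol(C))) else colnames(C)
    X <- cbind(X, C)
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  contrast <- c(0, 1, rep(0, ncol(X) - 2L))
  structure(list(X = X, contrast = contrast, group = g,
                 levels = levels(group), n = length(g)),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d subjects (%d vs %d), %d column(s) of nuisance covariates\n",
              x$n, sum(x$group == 1), sum(x$group == 0), ncol(x$X) - 2L))
  invisible(x)
}

# Stack a list of 3-D arrays into an n x V matrix restricted to mask voxels.
stack_maps <- function(maps, mask = NULL) {
  dims <- dim(maps[[1]])
  for (m in maps) if (!identical(dim(m), dims)) stop("map dimensions differ")
  if (is.null(mask)) mask <- array(TRUE, dims)
  Y <- do.call(rbind, lapply(maps, function(m) as.numeric(m[mask])))
  list(Y = Y, mask = mask, dims = dims)
}

#' Voxelwise GLM t-statistic for the group contrast
#'
#' Ordinary least squares at every voxel; the returned t is the contrast
#' estimate over its standard error, with `n - p` residual degrees of
#' freedom. Without covariates this reduces exactly to the classical
#' pooled-variance two-sample t-statistic. Voxels whose data are constant
#' across all subjects carry no signal and get t = 0; residual variances are
#' floored at a tiny relative value so perfectly separated voxels yield large
#' finite (rather than infinite) statistics.
#'
#' @param Y numeric matrix, subjects in rows, voxels in columns.
#' @param design a [design_matrix()].
#' @return numeric vector of t-values, one per column of `Y`.
#' @export
glm_tstat <- function(Y, design) {
  stopifnot(inherits(design, "design_matrix"))
  Y <- as.matrix(Y)
  if (!all(is.finite(Y))) stop("data must be finite")
  X <- design$X
  n <- nrow(X)
  p <- ncol(X)
  if (nrow(Y) != n) stop("rows of Y must match the design")
  if (n - p < 3L) stop("need at least 3 residual degrees of freedom")
  glm_tstat_core(Y, X, design$contrast)
}

# Hot path shared with the permutation loop: plain OLS + contrast t.
glm_tstat_core <- function(Y, X, contrast, XtXinv = solve(crossprod(X))) {
  n <- nrow(X)
  p <- ncol(X)
  beta <- XtXinv %*% crossprod(X, Y)
  res <- Y - X %*% beta
  sigma2 <- colSums(res^2) / (n - p)
  est <- as.numeric(contrast %*% beta)
  vc <- as.numeric(contrast %*% XtXinv %*% contrast)
  scale2 <- colMeans(Y^2)
  floor2 <- 1e-24 * pmax(scale2, 1e-12)
  tval <- est / sqrt(pmax(sigma2, floor2) * vc)
  tval[colvar_zero(Y)] <- 0
  tval
}

# TRUE for columns (numerically) constant across subjects.
colvar_zero <- function(Y) {
  n <- nrow(Y)
  cm <- colMeans(Y)
  ssd <- colSums(Y^2) - n * cm^2
  ssd <= 1e-12 * pmax(colSums(Y^2), 1e-300)
}

#' Threshold-free cluster enhancement (TFCE)
#'
#' Integrates cluster extent and height over all thresholds: for voxel p,
#' `TFCE(p) = sum over h = dh, 2dh, ... <= max(stat) of e_h(p)^E * h^H * dh`,
#' where `e_h(p)` is the voxel count of the connected component containing p
#' in the supra-threshold set `{stat >= h}`. Only the positive part of the
#' map is enhanced; run `tfce(-stat, ...)` for the opposite direction.
#'
#' @param stat numeric 3-D array (finite).
#' @param H height exponent (canonical default 2).
#' @param E extent exponent (canonical default 0.5).
#' @param dh threshold step; default `max(stat)/100`.
#' @param connectivity neighborhood definition: 6, 18 or 26 (default).
#' @return numeric 3-D array of enhanced values (>= 0).
#' @export
tfce <- function(stat, H = 2, E = 0.5, dh = NULL, connectivity = 26L) {
  if (!is.array(stat) || length(dim(stat)) != 3L)
    stop("`stat` must be a 3-D array")
  if (!all(is.finite(stat))) stop("`stat` must be finite")
  mx <- max(stat)
  if (mx <= 0) return(array(0, dim = dim(stat)))
  if (is.null(dh)) dh <- mx / 100
  if (!(dh > 0)) stop("`dh` must be positive")
  out <- .tfce_cpp(as.numeric(stat), as.integer(dim(stat)), H, E, dh,
                   as.integer(connectivity))
  array(out, dim = dim(stat))
}

#' Connected-component labelling of a binary 3-D volume
#'
#' @param vol logical 3-D array.
#' @param connectivity 6, 18 or 26.
#' @return integer array of component labels (0 = background).
#' @export
label_components <- function(vol, connectivity = 26L) {
  if (!is.array(vol) || length(dim(vol)) != 3L)
    stop("`vol` must be a 3-D array")
  array(.cc_label_cpp(as.logical(vol), as.integer(dim(vol)),
                      as.integer(connectivity)), dim = dim(vol))
}

#' Permutation inference with TFCE and family-wise error correction
#'
#' Computes the observed voxelwise t-map and its TFCE enhancement in both
#' directions, then builds the null distribution of the map-wise maximum
#' statistic by permutation and converts it into FWE-corrected p-values:
#' `p_fwe(v) = (1 + #\{permutation maxima >= observed(v)\}) / (n_perm + 1)`.
#'
#' Permutation schemes: `"freedman_lane"` (default) refits the reduced
#' (nuisance-only) model and permutes its residuals, the standard scheme for
#' GLMs with nuisance covariates; `"labels"` permutes group assignments
#' directly. With the label scheme, if `n_perm` meets or exceeds the number
#' of distinguishable relabelings `choose(n, n1)`, the relabelings are
#' enumerated exhaustively (with a warning) and the p-values are exact.
#'
#' Voxels outside the analysis mask, and voxels with zero variance across
#' subjects, are excluded from the max-statistic computation and reported
#' with p = 1.
#'
#' @param maps list of per-subject numeric 3-D arrays (all one shape), e.g.
#'   binary lesion maps or thresholded disconnectome maps.
#' @param design a [design_matrix()].
#' @param n_perm number of permutations (>= 1); study-scale analyses
#'   conventionally use 5000.
#' @param seed integer seed for the permutation stream.
#' @param grid optional [volume_grid()] carried on the result.
#' @param statistic `"tfce"` (default) or `"t"` (max-t FWE, no enhancement).
#' @param scheme permutation scheme, see Details.
#' @param mask optional logical array restricting the analysis; default the
#'   union of nonzero voxels across subjects.
#' @param H,E,dh,connectivity TFCE parameters, see [tfce()]. `dh = NULL`
#'   rescales per map as max/100.
#' @return object of class `stat_map`: fields `t` (3-D array), and per
#'   direction (`g1_gt_g2`, `g2_gt_g1`) `tfce` and `p_fwe` arrays, plus
#'   `mask`, `n_perm` (effective count), `exhaustive`, `seed`, `directions`.
#' @export
permutation_fwe <- function(maps, design, n_perm = 5000L, seed = 1L,
                            grid = NULL, statistic = c("tfce", "t"),
                            scheme = c("freedman_lane", "labels"),
                            mask = NULL, H = 2, E = 0.5, dh = NULL,
                            connectivity = 26L) {
  stopifnot(inherits(design, "design_matrix"))
  statistic <- match.arg(statistic)
  scheme <- match.arg(scheme)
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("`n_perm` must be >= 1")
  if (is.null(mask)) {
    mask <- Reduce(`|`, lapply(maps, function(m) m != 0))
  }
  st <- stack_maps(maps, mask)
  Y <- st$Y
  dims <- st$dims
  n <- nrow(Y)
  if (n != design$n) stop("number of maps must match the design")
  nonconst <- !colvar_zero(Y)

  enhance <- function(tvec) {
    vol <- array(0, dims)
    vol[mask] <- tvec
    if (statistic == "t") {
      pos <- vol
      pos[pos < 0] <- 0
      neg <- -vol
      neg[neg < 0] <- 0
      list(pos = pos, neg = neg)
    } else {
      list(pos = tfce(vol, H, E, dh, connectivity),
           neg = tfce(-vol, H, E, dh, connectivity))
    }
  }

  t_obs <- glm_tstat(Y, design)
  obs <- enhance(t_obs)

  # permutation engine
  X <- design$X
  exhaustive <- FALSE
  if (scheme == "labels") {
    n1 <- sum(design$group == 1)
    n_distinct <- choose(n, n1)
    if (n_perm >= n_distinct) {
      warning(sprintf(
        "n_perm = %d meets or exceeds the %d distinguishable relabelings; using exhaustive enumeration",
        n_perm, n_distinct))
      exhaustive <- TRUE
      combos <- combn(n, n1)
      obs_set <- sort(which(design$group == 1))
      keep <- !apply(combos, 2L, function(cc) identical(sort(cc), obs_set))
      combos <- combos[, keep, drop = FALSE]
      n_perm <- ncol(combos)
    }
  } else {
    # Freedman-Lane: residualize against the reduced (nuisance-only) model
    Z <- X[, -2L, drop = FALSE]
    Hz <- Z %*% solve(crossprod(Z)) %*% t(Z)
    Ez <- Y - Hz %*% Y
    Yfit <- Hz %*% Y
    XtXinv_full <- solve(crossprod(X))
  }

  max_pos <- numeric(n_perm)
  max_neg <- numeric(n_perm)
  set.seed(derive_seed(seed, 7L))
  masked_nc <- nonconst
  for (j in seq_len(n_perm)) {
    if (scheme == "labels") {
      g <- integer(n)
      if (exhaustive) g[combos[, j]] <- 1L else g[sample.int(n, sum(design$group))] <- 1L
      Xp <- X
      Xp[, 2L] <- g
      tp <- glm_tstat_core(Y, Xp, design$contrast)
    } else {
      pi_j <- sample.int(n)
      Yp <- Yfit + Ez[pi_j, , drop = FALSE]
      tp <- glm_tstat_core(Yp, X, design$contrast, XtXinv_full)
    }
    tp[!masked_nc] <- 0
    en <- enhance(tp)
    max_pos[j] <- max(en$pos)
    max_neg[j] <- max(en$neg)
  }

  pmap <- function(obs_vol, maxima) {
    pv <- array(1, dims)
    v_obs <- obs_vol[mask]
    v_obs[!nonconst] <- -Inf
    cnt <- vapply(v_obs, function(o)
      if (!is.finite(o) && o < 0) n_perm else sum(maxima >= o), 0)
    pin <- (1 + cnt) / (n_perm + 1)
    pin[!nonconst] <- 1
    pv[mask] <- pin
    pv
  }

  t_vol <- array(0, dims)
  t_vol[mask] <- t_obs

  structure(list(
    grid = grid, t = t_vol,
    tfce = list(g1_gt_g2 = obs$pos, g2_gt_g1 = obs$neg),
    p_fwe = list(g1_gt_g2 = pmap(obs$pos, max_pos),
                 g2_gt_g1 = pmap(obs$neg, max_neg)),
    mask = mask, statistic = statistic, scheme = scheme,
    n_perm = n_perm, exhaustive = exhaustive, seed = as.integer(seed),
    directions = paste(design$levels, collapse = " vs "),
    max_null = list(g1_gt_g2 = max_pos, g2_gt_g1 = max_neg)),
    class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf(
    "<stat_map> %s; %s statistic, %d permutations%s\n  min p_fwe: %.4g (%s), %.4g (%s)\n",
    x$directions, x$statistic, x$n_perm,
    if (x$exhaustive) " (exhaustive)" else "",
    min(x$p_fwe$g1_gt_g2[x$mask]), "group1 > group2",
    min(x$p_fwe$g2_gt_g1[x$mask]), "group2 > group1"))
  invisible(x)
}

#' Binary map of FWE-significant voxels
#'
#' @param stat_map a [permutation_fwe()] result.
#' @param direction `"g1_gt_g2"` or `"g2_gt_g1"`.
#' @param alpha FWE-corrected significance level.
#' @return logical 3-D array (the disconnection-based map when applied to a
#'   disconnection analysis).
#' @export
significant_map <- function(stat_map, direction = c("g1_gt_g2", "g2_gt_g1"),
                            alpha = 0.05) {
  stopifnot(inherits(stat_map, "stat_map"))
  direction <- match.arg(direction)
  stat_map$p_fwe[[direction]] < alpha & stat_map$mask
}
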