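# Voxel-wise multi-modal group GLM.
#
# The group design combines categorical cells (age group x scanner),
# group-wise mean-centered scalar covariates (optionally split into
# group-specific columns), and voxel-wise imaging covariates (one 3D map per
# subject, expanded into cell-specific columns), so the design matrix varies
# by voxel. Inference: per-voxel OLS, t contrasts, and permutation max-T
# family-wise error control (Freedman-Lane residual permutation under the
# reduced model, optionally stratified).

#' Specify a voxel-wise multi-modal group model
#'
#' @param dependent Name of the dependent map stack (e.g. `"mperaf"`,
#'   `"sme"`, `"gmv"`).
#' @param cell_factors Character vector of cohort columns whose crossing
#'   defines the categorical cells (cell-means coding, no intercept).
#' @param scalar_covariates Named list; each element a list with `center`
#'   (`"groupwise_mean_center"` or `"none"`), `split` (logical: one column
#'   per age group) and optional `label`.
#' @param voxelwise_covariates Named list; each element a list with `split`
#'   (`"cell"` for cell-specific columns or `"none"`) and optional `label`.
#'   Voxel-wise covariates are mean-centered within their expansion cell at
#'   every voxel.
#' @param analysis_mask Logical 3D array (or vector) of analyzed voxels.
#' @return A list of class `group_model_spec`.
#' @export
group_model_spec <- function(dependent, cell_factors = c("age_group", "scanner"),
                             scalar_covariates = list(),
                             voxelwise_covariates = list(),
                             analysis_mask = NULL) {
  structure(list(dependent = dependent, cell_factors = cell_factors,
                 scalar_covariates = scalar_covariates,
                 voxelwise_covariates = voxelwise_covariates,
                 analysis_mask = analysis_mask),
            class = "group_model_spec")
}

# paper-style display label for a cell ("young_Skyra", "older_Verio")
cell_label <- function(group, scanner) {
  paste(ifelse(group == "old", "older", group), scanner, sep = "_")
}

#' Build the inclusive analysis mask
#'
#' Intersection of voxels that are finite and nonzero in every subject's map
#' of every listed modality ("inclusive mask of active voxels").
#'
#' @param ... Subject-by-voxel matrices (one per modality).
#' @param dim Optional spatial dim for the returned array.
#' @return Logical vector (or 3D array if `dim` given).
#' @export
build_inclusive_mask <- function(..., dim = NULL) {
  stacks <- list(...)
  stopifnot_msg(length(stacks) >= 1, "need at least one map stack")
  V <- ncol(stacks[[1]])
  keep <- rep(TRUE, V)
  for (s in stacks) {
    stopifnot_msg(ncol(s) == V, "map stacks must share the voxel grid")
    keep <- keep & apply(is.finite(s) & s != 0, 2L, all)
  }
  if (!any(keep)) stop("inclusive mask is empty", call. = FALSE)
  if (!is.null(dim)) array(keep, dim) else keep
}

#' Assemble per-voxel design matrices for a group model
#'
#' Produces the base (voxel-constant) design -- cell indicators plus scalar
#' covariates centered per policy and split by age group where requested --
#' and the voxel-wise covariate expansion. Column order is fixed: cells,
#' scalar covariates (in list order, young column before old when split),
#' then voxel-wise covariates expanded by cell.
#'
#' @param spec A [group_model_spec].
#' @param cohort Cohort data frame (needs the factor and covariate columns).
#' @param maps Named list of subject-by-voxel matrices for the voxel-wise
#'   covariates.
#' @return A list of class `group_designs` with `X0` (n x p0 base design),
#'   `vox` (per-covariate list: centered n x V matrices per cell column),
#'   `col_names`, `n`, `V`, `mask` (voxel logical), `dim`, `affine`.
#' @export
assemble_designs <- function(spec, cohort, maps = list()) {
  n <- nrow(cohort)
  grp <- cohort$age_group
  # categorical cells
  cells <- interaction(lapply(spec$cell_factors, function(f) cohort[[f]]),
                       drop = TRUE, lex.order = TRUE)
  if (identical(spec$cell_factors, c("age_group", "scanner"))) {
    lab <- cell_label(cohort$age_group, cohort$scanner)
    ord <- c(outer(c("Skyra", "Verio"), c("young", "older"),
                   function(s, g) paste(g, s, sep = "_")))
    lab <- factor(lab, levels = intersect(ord, unique(lab)))
  } else {
    lab <- factor(as.character(cells))
  }
  X0 <- stats::model.matrix(~ 0 + lab)
  colnames(X0) <- levels(lab)

  for (nm in names(spec$scalar_covariates)) {
    cfg <- spec$scalar_covariates[[nm]]
    label <- if (!is.null(cfg$label)) cfg$label else nm
    x <- cohort[[nm]]
    stopifnot_msg(!is.null(x), paste0("cohort lacks covariate ", nm))
    if (identical(cfg$center, "groupwise_mean_center"))
      x <- x - stats::ave(x, grp)
    if (isTRUE(cfg$split)) {
      for (g in c("young", "old")) {
        col <- ifelse(grp == g, x, 0)
        X0 <- cbind(X0, col)
        colnames(X0)[ncol(X0)] <- paste0(label, "_", g)
      }
    } else {
      X0 <- cbind(X0, x)
      colnames(X0)[ncol(X0)] <- label
    }
  }

  # voxelwise covariates: cell-specific columns, centered within cell per voxel
  vox <- list()
  vox_names <- character(0)
  V <- NULL
  for (nm in names(spec$voxelwise_covariates)) {
    cfg <- spec$voxelwise_covariates[[nm]]
    label <- if (!is.null(cfg$label)) cfg$label else nm
    M <- maps[[nm]]
    stopifnot_msg(!is.null(M), paste0("missing voxelwise covariate map: ", nm))
    stopifnot_msg(nrow(M) == n, paste0("map stack ", nm,
                                       " must have one row per subject"))
    miss <- rowSums(!is.finite(M)) > 0
    if (any(miss))
      stop("non-finite voxelwise covariate ", nm, " for subject ",
           cohort$subject_id[which(miss)[1]], call. = FALSE)
    if (is.null(V)) V <- ncol(M) else
      stopifnot_msg(ncol(M) == V, "voxelwise map grids differ")
    if (identical(cfg$split, "none")) {
      Mc <- sweep(M, 2L, colMeans(M))
      vox[[paste0(label)]] <- list(rows = seq_len(n), mat = Mc)
      vox_names <- c(vox_names, label)
    } else {
      for (lv in levels(lab)) {
        rows <- which(lab == lv)
        Mc <- sweep(M[rows, , drop = FALSE], 2L,
                    colMeans(M[rows, , drop = FALSE]))
        # paper-style voxelwise names use "old", not "older"
        cn <- paste0(label, "_", sub("^older_", "old_", lv))
        vox[[cn]] <- list(rows = rows, mat = Mc)
        vox_names <- c(vox_names, cn)
      }
    }
  }

  mask <- spec$analysis_mask
  dims <- if (is.array(mask)) dim(mask) else NULL
  if (!is.null(mask)) mask <- as.vector(mask)
  if (is.null(V)) V <- if (!is.null(mask)) length(mask) else NA_integer_
  if (is.null(mask) && !is.na(V)) mask <- rep(TRUE, V)

  structure(list(X0 = X0, vox = vox,
                 col_names = c(colnames(X0), vox_names),
                 n = n, V = V, mask = mask, dim = dims,
                 cells = lab),
            class = "group_designs")
}

# materialize the design matrix at voxel v (full-grid index)
design_at <- function(designs, v) {
  X <- designs$X0
  for (nm in names(designs$vox)) {
    col <- numeric(designs$n)
    vx <- designs$vox[[nm]]
    col[vx$rows] <- vx$mat[, v]
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- nm
  }
  X
}

#' Fit the group GLM at every voxel
#'
#' Independent ordinary least squares per voxel. Voxels where the per-voxel
#' design is rank deficient (possible when a voxel-wise covariate is locally
#' constant) are masked out and reported, not imputed. With no voxel-wise
#' covariates the fit reduces to a single standard group GLM applied to all
#' voxels at once.
#'
#' @param designs A `group_designs` from [assemble_designs()].
#' @param Y Subject-by-voxel matrix of the dependent maps (full grid).
#' @return A list of class `group_fit`: `betas` (p x V, NA outside mask),
#'   `sigma2`, `df`, `ok` (voxel usable), plus design bookkeeping.
#' @export
fit_voxelwise <- function(designs, Y) {
  stopifnot_msg(inherits(designs, "group_designs"), "need group_designs")
  stopifnot_msg(nrow(Y) == designs$n, "Y must have one row per subject")
  mask <- if (is.null(designs$mask)) rep(TRUE, ncol(Y)) else designs$mask
  stopifnot_msg(length(mask) == ncol(Y), "mask length must match voxels")
  vsel <- which(mask)
  p <- length(designs$col_names)
  V <- ncol(Y)
  betas <- matrix(NA_real_, p, V, dimnames = list(designs$col_names, NULL))
  sigma2 <- rep(NA_real_, V)
  ok <- rep(FALSE, V)
  df <- designs$n - p

  if (length(designs$vox) == 0) {
    X <- designs$X0
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
      stop("group design is rank deficient", call. = FALSE)
    B <- qr.coef(qrX, Y[, vsel, drop = FALSE])
    res <- Y[, vsel, drop = FALSE] - X %*% B
    betas[, vsel] <- B
    sigma2[vsel] <- colSums(res^2) / df
    ok[vsel] <- TRUE
  } else {
    for (v in vsel) {
      X <- design_at(designs, v)
      qrX <- qr(X)
      if (qrX$rank < ncol(X)) next
      b <- qr.coef(qrX, Y[, v])
      r <- Y[, v] - X %*% b
      betas[, v] <- b
      sigma2[v] <- sum(r^2) / df
      ok[v] <- TRUE
    }
    if (sum(ok) < 0.5 * length(vsel))
      stop(sprintf("pervasive rank deficiency: only %d of %d masked voxels estimable",
                   sum(ok), length(vsel)), call. = FALSE)
  }
  structure(list(betas = betas, sigma2 = sigma2, df = df, ok = ok,
                 designs = designs, Y = Y),
            class = "group_fit")
}

#' Compute a t-statistic map for a contrast
#'
#' \eqn{t = c'\beta / \sqrt{\hat\sigma^2 c'(X'X)^{-1}c}} per voxel, with
#' error degrees of freedom `n - p`.
#'
#' @param fit A `group_fit`.
#' @param weights Contrast weights over the model columns (named vectors are
#'   matched to column names; unnamed must give all `p` weights).
#' @param name Contrast label.
#' @return A list of class `stat_map`: `t` (vector over the full grid, NA
#'   outside usable voxels), `df`, `name`, `weights`, `dim`.
#' @export
t_contrast <- function(fit, weights, name = "contrast") {
  cn <- fit$designs$col_names
  cvec <- contrast_vector(weights, cn)
  tmap <- rep(NA_real_, ncol(fit$Y))
  vsel <- which(fit$ok)
  if (length(fit$designs$vox) == 0) {
    X <- fit$designs$X0
    cXXc <- drop(t(cvec) %*% solve(crossprod(X), cvec))
    num <- drop(t(cvec) %*% fit$betas[, vsel, drop = FALSE])
    tmap[vsel] <- num / sqrt(fit$sigma2[vsel] * cXXc)
  } else {
    for (v in vsel) {
      X <- design_at(fit$designs, v)
      cXXc <- drop(t(cvec) %*% solve(crossprod(X), cvec))
      tmap[v] <- sum(cvec * fit$betas[, v]) / sqrt(fit$sigma2[v] * cXXc)
    }
  }
  structure(list(t = tmap, df = fit$df, name = name, weights = cvec,
                 dim = fit$designs$dim),
            class = "stat_map")
}

contrast_vector <- function(weights, col_names) {
  p <- length(col_names)
  if (!is.null(names(weights))) {
    miss <- setdiff(names(weights), col_names)
    stopifnot_msg(length(miss) == 0,
                  paste0("unknown contrast columns: ", paste(miss, collapse = ", ")))
    cvec <- stats::setNames(rep(0, p), col_names)
    cvec[names(weights)] <- weights
    cvec <- unname(cvec)
  } else {
    stopifnot_msg(length(weights) == p, "contrast length must match columns")
    cvec <- as.numeric(weights)
  }
  stopifnot_msg(any(cvec != 0), "contrast must not be all zero")
  cvec
}

# orthonormal basis of the null space of c' (nuisance directions)
null_space <- function(cvec) {
  p <- length(cvec)
  qr.Q(qr(cbind(cvec, diag(p))))[, 2:p, drop = FALSE]
}

#' Permutation max-T family-wise-error inference
#'
#' One-sided voxel-level FWE control for a t contrast by the maximum-statistic
#' permutation distribution. Nuisance covariates are handled by
#' Freedman-Lane residual permutation under the reduced model; permutations
#' can be restricted to exchangeability strata (e.g. scanner). Surviving
#' voxels are grouped by 26-connectivity and clusters smaller than `k`
#' discarded. `method = "bonferroni"` gives the parametric fallback.
#'
#' @param fit A `group_fit`.
#' @param weights Contrast weights (see [t_contrast()]); the test is
#'   one-sided in the direction of the contrast.
#' @param alpha Family-wise error level.
#' @param k Cluster extent threshold in voxels.
#' @param method `"permutation_maxT"` (default) or `"bonferroni"`.
#' @param n_perm Number of permutations (the observed labeling is included
#'   as one member of the null distribution).
#' @param seed Permutation seed; fixed seed gives identical thresholds.
#' @param strata Optional factor of exchangeability blocks (length n).
#' @param affine Optional 4x4 affine; when given, cluster peaks are reported
#'   in mm, otherwise as voxel indices.
#' @return A list of class `fwe_result`: `stat` (the observed [t_contrast()]
#'   map), `fwe_p` (voxel-wise FWE p-values), `supra` (logical vector after
#'   extent thresholding), `clusters` (cluster table with size, peak t, peak
#'   mm coordinates, FWE p), `maxT` (null distribution), `threshold`.
#' @export
fwe_threshold <- function(fit, weights, alpha = 0.05, k = 10L,
                          method = c("permutation_maxT", "bonferroni"),
                          n_perm = 2000L, seed = 1L, strata = NULL,
                          affine = NULL) {
  method <- match.arg(method)
  stat <- t_contrast(fit, weights)
  vsel <- which(fit$ok)
  stopifnot_msg(length(vsel) > 0, "no usable voxels")
  n <- fit$designs$n

  if (method == "bonferroni") {
    thr <- stats::qt(1 - alpha / length(vsel), df = fit$df)
    fwe_p <- rep(NA_real_, length(stat$t))
    fwe_p[vsel] <- pmin(1, stats::pt(stat$t[vsel], df = fit$df,
                                     lower.tail = FALSE) * length(vsel))
    supra <- !is.na(stat$t) & stat$t > thr
  } else {
    if (n < 10) stop("too few permutable units (< 10)", call. = FALSE)
    cvec <- stat$weights
    perms <- make_permutations(n, n_perm, seed, strata)
    n_tot <- ncol(perms)  # includes identity
    maxT <- rep(-Inf, n_tot)
    t_obs <- rep(NA_real_, length(stat$t))

    single <- length(fit$designs$vox) == 0
    Cv <- null_space(cvec)
    if (single) {
      # one design for all voxels: loop over permutations, vectorize voxels
      X <- fit$designs$X0
      qrX <- qr(X)
      Z <- X %*% Cv
      qrZ <- qr(Z)
      cXXc <- drop(t(cvec) %*% solve(crossprod(X), cvec))
      dfv <- n - ncol(X)
      Yv <- fit$Y[, vsel, drop = FALSE]
      G <- qr.coef(qrZ, Yv)
      Eres <- Yv - Z %*% G
      Zg <- Z %*% G
      for (j in seq_len(n_tot)) {
        Ystar <- Zg + Eres[perms[, j], , drop = FALSE]
        B <- qr.coef(qrX, Ystar)
        s2 <- colSums((Ystar - X %*% B)^2) / dfv
        tv <- drop(t(cvec) %*% B) / sqrt(s2 * cXXc)
        maxT[j] <- max(tv)
        if (j == 1L) t_obs[vsel] <- tv
      }
    } else {
      # voxel-dependent designs: loop over voxels, vectorize permutations
      for (vv in vsel) {
        X <- design_at(fit$designs, vv)
        qrX <- qr(X)
        Z <- X %*% Cv
        cXXc <- drop(t(cvec) %*% solve(crossprod(X), cvec))
        dfv <- n - ncol(X)
        yv <- fit$Y[, vv]
        g <- qr.coef(qr(Z), yv)
        e <- yv - drop(Z %*% g)
        Ystar <- matrix(e[perms], n, n_tot) + drop(Z %*% g)
        B <- qr.coef(qrX, Ystar)
        s2 <- colSums((Ystar - X %*% B)^2) / dfv
        tv <- drop(t(cvec) %*% B) / sqrt(s2 * cXXc)
        maxT <- pmax(maxT, tv)
        t_obs[vv] <- tv[1]
      }
    }
    fwe_p <- rep(NA_real_, length(stat$t))
    fwe_p[vsel] <- vapply(t_obs[vsel],
                          function(tt) mean(maxT >= tt - 1e-12), 0)
    stat$t[vsel] <- t_obs[vsel]   # FL observed t (identity permutation)
    supra <- !is.na(fwe_p) & fwe_p <= alpha
    thr <- if (any(supra)) min(stat$t[supra]) else
      stats::quantile(maxT, 1 - alpha, names = FALSE, type = 1)
  }

  clusters <- cluster_table(supra, stat, fwe_p, k,
                            dim = fit$designs$dim, affine = affine)
  keep <- rep(FALSE, length(supra))
  if (nrow(clusters$table) > 0) keep[clusters$voxels] <- TRUE
  structure(list(stat = stat, fwe_p = fwe_p, supra = keep,
                 clusters = clusters$table,
                 maxT = if (method == "permutation_maxT") maxT else NULL,
                 threshold = thr, alpha = alpha, k = k, method = method),
            class = "fwe_result")
}

# stratified permutation index matrix; column 1 is the identity
make_permutations <- function(n, n_perm, seed, strata = NULL) {
  if (is.null(strata)) strata <- rep(1L, n)
  stopifnot_msg(length(strata) == n, "strata length must be n")
  idx <- seq_len(n)
  with_seed(seed, {
    P <- matrix(0L, n, n_perm + 1L)
    P[, 1] <- idx
    for (j in seq_len(n_perm) + 1L) {
      pj <- idx
      for (s in unique(strata)) {
        rows <- which(strata == s)
        pj[rows] <- rows[sample.int(length(rows))]
      }
      P[, j] <- pj
    }
    P
  })
}

# label supra-threshold voxels by 26-connectivity, drop clusters < k, and
# tabulate size / peak t / peak coordinates / peak FWE p.
cluster_table <- function(supra, stat, fwe_p, k, dim = NULL, affine = NULL) {
  empty <- data.frame(cluster = integer(0), size = integer(0),
                      peak_t = numeric(0), peak_x = numeric(0),
                      peak_y = numeric(0), peak_z = numeric(0),
                      fwe_p = numeric(0))
  if (!any(supra)) return(list(table = empty, voxels = integer(0)))
  if (is.null(dim)) {
    # no spatial structure: treat each voxel as its own cluster of size 1
    vox <- which(supra)
    if (k > 1) return(list(table = empty, voxels = integer(0)))
    tab <- data.frame(cluster = seq_along(vox), size = 1L,
                      peak_t = stat$t[vox], peak_x = NA_real_,
                      peak_y = NA_real_, peak_z = NA_real_,
                      fwe_p = fwe_p[vox])
    return(list(table = tab, voxels = vox))
  }
  labs <- label_components_26(array(supra, dim))
  ids <- setdiff(unique(as.vector(labs)), 0L)
  rows <- list()
  keep_vox <- integer(0)
  cl_id <- 0L
  for (id in ids) {
    vox <- which(labs == id)
    if (length(vox) < k) next
    cl_id <- cl_id + 1L
    peak <- vox[which.max(stat$t[vox])]
    ijk <- arrayInd(peak, dim)
    mm <- if (!is.null(affine)) voxel_to_mm(ijk, affine) else ijk
    rows[[cl_id]] <- data.frame(cluster = cl_id, size = length(vox),
                                peak_t = stat$t[peak], peak_x = mm[1],
                                peak_y = mm[2], peak_z = mm[3],
                                fwe_p = fwe_p[peak])
    keep_vox <- c(keep_vox, vox)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else empty
  list(table = tab[order(-tab$size), , drop = FALSE], voxels = keep_vox)
}

# connected-component labeling with 26-neighborhood
label_components_26 <- function(mask) {
  d <- dim(mask)
  labs <- array(0L, d)
  todo <- which(mask)
  nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  cur <- 0L
  for (start in todo) {
    if (labs[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    labs[start] <- cur
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      ijk <- arrayInd(v, d)
      cand <- sweep(nb, 2L, as.integer(ijk), `+`)
      okc <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
        cand[, 2] >= 1 & cand[, 2] <= d[2] &
        cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[okc, , drop = FALSE]
      lin <- cand[, 1] + (cand[, 2] - 1L) * d[1] +
        (cand[, 3] - 1L) * d[1] * d[2]
      new <- lin[mask[lin] & labs[lin] == 0L]
      labs[new] <- cur
      stack <- c(stack, new)
    }
  }
  labs
}

#' Overlap of two thresholded maps
#'
#' Voxel-wise logical AND of two binarized thresholded maps (e.g. the
#' young > older resting-amplitude contrast and the older > young encoding
#' contrast), with the intersection clusters tabulated.
#'
#' @param a,b Logical vectors/arrays of identical shape (e.g. the `supra`
#'   component of [fwe_threshold()] results), or `fwe_result` objects.
#' @param stat Optional `stat_map` used for peak values in the table.
#' @param dim Spatial dimensions (needed when `a`, `b` are plain vectors).
#' @param k Extent threshold applied to the overlap clusters.
#' @return A list: `overlap` (logical), `clusters` (table).
#' @export
overlap_maps <- function(a, b, stat = NULL, dim = NULL, k = 1L) {
  if (inherits(a, "fwe_result")) { if (is.null(stat)) stat <- a$stat
    if (is.null(dim)) dim <- a$stat$dim; a <- a$supra }
  if (inherits(b, "fwe_result")) b <- b$supra
  stopifnot_msg(length(a) == length(b), "grid mismatch between the two maps")
  ov <- as.vector(a) & as.vector(b)
  if (is.null(stat))
    stat <- structure(list(t = as.numeric(ov), df = NA, dim = dim),
                      class = "stat_map")
  cl <- cluster_table(ov, stat, fwe_p = rep(NA_real_, length(ov)), k = k,
                      dim = dim)
  list(overlap = if (!is.null(dim)) array(ov, dim) else ov,
       clusters = cl$table)
}
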