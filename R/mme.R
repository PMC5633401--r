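#' Design structure for the animal model
#'
#' Builds the incidence matrices of the linear mixed model
#' y = Xb + Zu + e: X maps records to management units (one-hot, no
#' intercept — units are the only fixed effects) and Z maps records to
#' individuals (the identity permutation in the one-record-per-individual
#' setting).
#'
#' @param units A `unit_assignment` (one record per individual).
#' @return A `design_structure`: list with matrices `X`, `Z`,
#'   `unit_labels` and `individual_ids`.
#' @export
build_design <- function(units) {
  ids <- units$id
  labels <- sort(unique(units$unit))
  X <- outer(units$unit, labels, "==") + 0
  dimnames(X) <- list(ids, labels)
  if (any(colSums(X) == 0)) stop("empty management unit", call. = FALSE)
  Z <- diag(length(ids))
  dimnames(Z) <- list(ids, ids)
  structure(list(X = X, Z = Z, unit_labels = labels, individual_ids = ids),
            class = "design_structure")
}

#' Variance components from heritability
#'
#' Under the standardized-phenotype convention (y scaled to unit
#' variance) the additive genetic variance is h2, the residual variance
#' 1 - h2, and the mixed-model variance ratio is
#' lambda = sigma_e^2 / sigma_u^2 = (1 - h2) / h2.
#'
#' @param h2 Narrow-sense heritability, strictly in (0, 1).
#' @return A `variance_model`: list with `h2`, `sigma_u2`, `sigma_e2`,
#'   `lambda`.
#' @export
variance_model_from_h2 <- function(h2) {
  if (!is.numeric(h2) || length(h2) != 1L || h2 <= 0 || h2 >= 1) {
    stop("h2 must lie strictly in (0, 1)", call. = FALSE)
  }
  variance_model(sigma_u2 = h2, sigma_e2 = 1 - h2)
}

#' Variance model from explicit components
#'
#' For externally estimated variance components (e.g. REML output).
#'
#' @param sigma_u2 Additive genetic variance (> 0).
#' @param sigma_e2 Residual variance (> 0).
#' @return A `variance_model`.
#' @export
variance_model <- function(sigma_u2, sigma_e2) {
  if (sigma_u2 <= 0 || sigma_e2 <= 0) {
    stop("variance components must be positive", call. = FALSE)
  }
  structure(list(h2 = sigma_u2 / (sigma_u2 + sigma_e2),
                 sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
                 lambda = sigma_e2 / sigma_u2),
            class = "variance_model")
}

#' Prediction error (co)variance by fixed-effect absorption
#'
#' Absorbs the fixed management-unit effects with the projection
#' M = I - X (X'X)^- X' and inverts only the random-effect block:
#' PEV = (Z'MZ + K^-1 lambda)^-1 sigma_e^2 = C22 sigma_e^2. This avoids
#' the inverse of the full coefficient matrix of the mixed model
#' equations and is the production route; [pev_full_mme()] is the direct
#' route used as its cross-check. PEV depends only on the design, the
#' kernel and lambda — phenotype values never enter.
#'
#' @param design A `design_structure`.
#' @param k A `kernel_matrix` over the design's individuals (regularized
#'   via [ensure_invertible()] if needed).
#' @param vm A `variance_model`.
#' @return A `pev_result`: list with matrices `pev` and `c22`
#'   (`pev = c22 * sigma_e2`), the `variance_model`, `kernel_kind` and
#'   `ids`.
#' @export
pev_absorption <- function(design, k, vm) {
  km <- align_kernel(k, design$individual_ids)
  X <- design$X; Z <- design$Z
  XtX <- crossprod(X)
  M <- diag(nrow(X)) - X %*% MASS::ginv(XtX) %*% t(X)
  Kinv <- kernel_inverse(km)
  coef <- crossprod(Z, M %*% Z) + Kinv * vm$lambda
  c22 <- sym_solve(coef)
  new_pev_result(c22, vm, kernel_kind(km), design$individual_ids)
}

#' Prediction error (co)variance from the full MME inverse
#'
#' Builds the full coefficient matrix
#' \[X'X, X'Z; Z'X, Z'Z + K^-1 lambda\], takes a Moore-Penrose
#' generalized inverse, and extracts the C22 block. Algebraically
#' identical to [pev_absorption()]; kept as the independent route.
#'
#' @inheritParams pev_absorption
#' @return A `pev_result`.
#' @export
pev_full_mme <- function(design, k, vm) {
  km <- align_kernel(k, design$individual_ids)
  X <- design$X; Z <- design$Z
  Kinv <- kernel_inverse(km)
  coef <- rbind(
    cbind(crossprod(X), crossprod(X, Z)),
    cbind(crossprod(Z, X), crossprod(Z) + Kinv * vm$lambda)
  )
  Cinv <- MASS::ginv(coef)
  idx <- ncol(X) + seq_len(ncol(Z))
  c22 <- Cinv[idx, idx, drop = FALSE]
  dimnames(c22) <- list(design$individual_ids, design$individual_ids)
  new_pev_result(c22, vm, kernel_kind(km), design$individual_ids)
}

new_pev_result <- function(c22, vm, kind, ids) {
  c22 <- (c22 + t(c22)) / 2
  dimnames(c22) <- list(ids, ids)
  structure(list(pev = c22 * vm$sigma_e2, c22 = c22, variance_model = vm,
                 kernel_kind = kind, ids = ids),
            class = "pev_result")
}

#' @export
print.pev_result <- function(x, ...) {
  cat(sprintf(
    "<pev_result: %d individuals, kernel %s, h2 = %.3g (lambda = %.3g)>\n",
    length(x$ids), x$kernel_kind, x$variance_model$h2, x$variance_model$lambda))
  invisible(x)
}

align_kernel <- function(k, ids) {
  if (!all(ids %in% rownames(k))) {
    stop("kernel does not cover all individuals in the design", call. = FALSE)
  }
  kernel_matrix(as.matrix(k)[ids, ids, drop = FALSE], kind = kernel_kind(k),
                jitter_applied = attr(k, "jitter_applied"))
}

kernel_inverse <- function(k) {
  km <- ensure_invertible(k)
  sym_solve(as.matrix(km))
}

# Symmetric solve: Cholesky when PD, eigen-based fallback otherwise.
sym_solve <- function(m) {
  m <- (m + t(m)) / 2
  out <- tryCatch(chol2inv(chol(m)), error = function(e) NULL)
  if (is.null(out)) {
    e <- eigen(m, symmetric = TRUE)
    if (min(e$values) <= 1e-12 * max(abs(e$values))) {
      stop("matrix numerically singular in mixed-model solve", call. = FALSE)
    }
    out <- e$vectors %*% (t(e$vectors) / e$values)
  }
  dimnames(out) <- dimnames(m)
  (out + t(out)) / 2
}
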