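#' Connectedness results
#'
#' Container returned by the pairwise statistics and filled in by
#' [summarize_across_units()]: the n x n pairwise matrix over
#' individuals, the U x U matrix over management-unit pairs, and the
#' overall scalar average over distinct cross-unit pairs.
#'
#' @name connectedness_result
NULL

new_connectedness_result <- function(statistic, pairwise, pev, kernel = NULL,
                                     summary_mode = NA_character_) {
  structure(list(statistic = statistic, pairwise = pairwise,
                 unit_matrix = NULL, overall = NA_real_,
                 summary_mode = summary_mode,
                 kernel_kind = pev$kernel_kind,
                 h2 = pev$variance_model$h2,
                 pev = pev, kernel = kernel, ids = pev$ids),
            class = "connectedness_result")
}

#' @export
print.connectedness_result <- function(x, ...) {
  cat(sprintf("<connectedness_result: %s, kernel %s, h2 = %.3g>\n",
              x$statistic, x$kernel_kind, x$h2))
  if (!is.na(x$overall)) {
    cat(sprintf("  across-unit average (%s): %.4g\n", x$summary_mode,
                x$overall))
  }
  invisible(x)
}

#' Pairwise prediction error variance of differences (PEVD)
#'
#' PEVD_ij = (C22_ii + C22_jj - 2 C22_ij) sigma_e^2, reported in the
#' scaled form (divided by the additive genetic variance), i.e.
#' lambda (C22_ii + C22_jj - 2 C22_ij), which is unitless and invariant
#' to the absolute scale of the variance components at fixed lambda.
#' Small PEVD means the pair is well connected.
#'
#' @param pev A `pev_result`.
#' @return A `connectedness_result` with statistic `"PEVD"`.
#' @export
pevd_pairwise <- function(pev) {
  c22 <- pev$c22
  d <- diag(c22)
  lam <- pev$variance_model$lambda
  m <- lam * (outer(d, d, "+") - 2 * c22)
  new_connectedness_result("PEVD", m, pev)
}

#' Pairwise coefficient of determination (CD)
#'
#' CD_ij = 1 - lambda (C22_ii + C22_jj - 2 C22_ij) / (K_ii + K_jj -
#' 2 K_ij): the reliability of the predicted difference, which penalizes
#' connectedness obtained merely by comparing near-identical relatives.
#' Pairs with a zero kernel denominator (identical relatedness rows) are
#' undefined, set to `NA` and excluded from summaries with a warning.
#'
#' @param pev A `pev_result`.
#' @param k The same `kernel_matrix` used to build `pev`.
#' @return A `connectedness_result` with statistic `"CD"`.
#' @export
cd_pairwise <- function(pev, k) {
  if (!identical(kernel_kind(k), pev$kernel_kind)) {
    warning("kernel kind differs from the one recorded in the PEV result")
  }
  km <- as.matrix(align_kernel(k, pev$ids))
  c22 <- pev$c22
  lam <- pev$variance_model$lambda
  num <- outer(diag(c22), diag(c22), "+") - 2 * c22
  den <- outer(diag(km), diag(km), "+") - 2 * km
  undef <- abs(den) < 1e-12
  diag(undef) <- TRUE                    # self-pairs are always undefined
  m <- 1 - lam * num / den
  m[undef] <- NA_real_
  n_undef <- (sum(undef) - nrow(m)) / 2
  if (n_undef > 0) {
    warning(sprintf(
      "%d pair(s) with zero relatedness-difference denominator set to NA",
      n_undef))
  }
  new_connectedness_result("CD", m, pev, kernel = k)
}

#' Pairwise prediction error correlation (r)
#'
#' r_ij = PEC_ij / sqrt(PEV_i PEV_j): the correlation between prediction
#' errors. Zero when no information flows between the two individuals;
#' bounded in [-1, 1] by Cauchy-Schwarz.
#'
#' @param pev A `pev_result` with strictly positive PEV diagonal.
#' @return A `connectedness_result` with statistic `"r"`.
#' @export
r_pairwise <- function(pev) {
  d <- diag(pev$pev)
  if (any(d <= 0)) {
    stop("PEV diagonal must be strictly positive for r", call. = FALSE)
  }
  m <- pev$pev / sqrt(outer(d, d))
  new_connectedness_result("r", m, pev, summary_mode = "pair_average")
}

#' Contrast vector between two management units
#'
#' The vector with 1/n_i on members of unit `i_unit`, -1/n_j on members
#' of unit `j_unit` and 0 elsewhere; it sums to zero exactly.
#'
#' @param units A `unit_assignment`.
#' @param i_unit,j_unit Distinct unit labels.
#' @param ids Ordering of individuals for the vector (defaults to the
#'   assignment's id order; pass the PEV result's `ids` to match it).
#' @return Named numeric vector summing to zero.
#' @export
contrast_vector <- function(units, i_unit, j_unit, ids = units$id) {
  if (identical(i_unit, j_unit)) {
    stop("contrast requires two distinct units", call. = FALSE)
  }
  lab <- units$unit[match(ids, units$id)]
  if (!(i_unit %in% lab) || !(j_unit %in% lab)) {
    stop("unknown unit label: ",
         paste(setdiff(c(i_unit, j_unit), lab), collapse = ", "),
         call. = FALSE)
  }
  x <- numeric(length(ids))
  names(x) <- ids
  x[lab == i_unit] <- 1 / sum(lab == i_unit)
  x[lab == j_unit] <- -1 / sum(lab == j_unit)
  x
}

#' PEVD of a contrast
#'
#' x'C22 x sigma_e^2 in scaled form, i.e. lambda x'C22 x. For singleton
#' units this reduces to the pairwise PEVD entry.
#'
#' @param pev A `pev_result`.
#' @param x Contrast vector indexed like `pev$ids`.
#' @return Scalar scaled PEVD of the contrast.
#' @export
pevd_contrast <- function(pev, x) {
  x <- x[pev$ids]
  drop(pev$variance_model$lambda * crossprod(x, pev$c22 %*% x))
}

#' CD of a contrast
#'
#' 1 - lambda x'C22 x / x'K x; at most 1 for positive semi-definite
#' inputs, and the pairwise CD entry when both units are singletons.
#'
#' @param pev A `pev_result`.
#' @param k The kernel used to build `pev`.
#' @param x Contrast vector indexed like `pev$ids`.
#' @return Scalar CD of the contrast.
#' @export
cd_contrast <- function(pev, k, x) {
  x <- x[pev$ids]
  km <- as.matrix(align_kernel(k, pev$ids))
  den <- drop(crossprod(x, km %*% x))
  if (abs(den) < 1e-12) {
    stop("contrast has zero kernel variance (x'Kx = 0): CD undefined",
         call. = FALSE)
  }
  1 - pev$variance_model$lambda * drop(crossprod(x, pev$c22 %*% x)) / den
}

#' Group-ratio r summary between two units
#'
#' sum of cross-block PECs over the square root of the product of summed
#' within-block PEVs. A reasonable summary for pedigree kernels, but for
#' genomic-type kernels with exactly two management units it degenerates
#' (a warning is emitted); pair averaging is the default r summary.
#'
#' @param pev A `pev_result`.
#' @param units A `unit_assignment` covering `pev$ids`.
#' @param i_unit,j_unit Distinct unit labels.
#' @return Scalar group-ratio r.
#' @export
r_group_summary <- function(pev, units, i_unit, j_unit) {
  lab <- units$unit[match(pev$ids, units$id)]
  bi <- which(lab == i_unit); bj <- which(lab == j_unit)
  if (!length(bi) || !length(bj)) {
    stop("unknown or empty unit label", call. = FALSE)
  }
  if (pev$kernel_kind %in% c("G", "G05", "Gs", "H") &&
      length(unique(lab)) == 2L) {
    warning("group-ratio r with a genomic-type kernel and two management ",
            "units is unreliable; prefer pair averaging")
  }
  num <- sum(pev$pev[bi, bj])
  d1 <- sum(pev$pev[bi, bi]); d2 <- sum(pev$pev[bj, bj])
  if (d1 <= 0 || d2 <= 0) {
    stop("nonpositive within-block PEV sum", call. = FALSE)
  }
  num / sqrt(d1 * d2)
}

#' Across-unit connectedness summary
#'
#' Fills the unit-pair matrix and the overall average of a
#' connectedness result. `"contrast"` evaluates the statistic on the
#' mean-difference contrast of each unit pair (default for PEVD and CD);
#' `"pair_average"` averages the pairwise entries over all cross-unit
#' individual pairs (default for r); `"group_ratio"` applies the summed
#' PEC/PEV ratio (r only). The overall value is the unweighted mean over
#' distinct unit pairs.
#'
#' @param result A `connectedness_result` from one of the pairwise
#'   functions.
#' @param units A `unit_assignment` covering the result's individuals.
#' @param mode Summary mode; defaults to `"contrast"` for PEVD/CD and
#'   `"pair_average"` for r.
#' @return The `connectedness_result` with `unit_matrix`, `overall` and
#'   `summary_mode` filled in.
#' @export
summarize_across_units <- function(result, units,
                                   mode = c("default", "contrast",
                                            "pair_average", "group_ratio")) {
  mode <- match.arg(mode)
  if (mode == "default") {
    mode <- if (result$statistic == "r") "pair_average" else "contrast"
  }
  if (mode == "group_ratio" && result$statistic != "r") {
    stop("group_ratio summary applies to the r statistic only", call. = FALSE)
  }
  lab <- units$unit[match(result$ids, units$id)]
  if (anyNA(lab)) stop("unit assignment does not cover all individuals",
                       call. = FALSE)
  labels <- sort(unique(lab))
  U <- length(labels)
  if (U < 2L) stop("need at least two management units to summarize",
                   call. = FALSE)
  # aggregated block sums make every mode a U x U computation: for the
  # mean-difference contrast, x'Qx = S_aa/n_a^2 + S_bb/n_b^2 -
  # 2 S_ab/(n_a n_b) with S = Mu' Q Mu the unit-block sums of Q
  Mu <- outer(lab, labels, "==") + 0
  nu <- colSums(Mu)
  lam <- result$pev$variance_model$lambda
  block_quad <- function(Q) {
    S <- crossprod(Mu, Q %*% Mu)
    d <- diag(S) / nu^2
    outer(d, d, "+") - 2 * S / outer(nu, nu)
  }
  um <- switch(
    mode,
    contrast = {
      if (result$statistic == "PEVD") {
        lam * block_quad(result$pev$c22)
      } else if (result$statistic == "CD") {
        km <- as.matrix(align_kernel(result$kernel, result$ids))
        den <- block_quad(km)
        if (any(abs(den[upper.tri(den)]) < 1e-12)) {
          stop("contrast with zero kernel variance (x'Kx = 0): CD undefined",
               call. = FALSE)
        }
        1 - lam * block_quad(result$pev$c22) / den
      } else stop("contrast summary applies to PEVD or CD", call. = FALSE)
    },
    pair_average = {
      P <- result$pairwise
      W <- !is.na(P) + 0
      P[is.na(P)] <- 0
      crossprod(Mu, P %*% Mu) / crossprod(Mu, W %*% Mu)
    },
    group_ratio = {
      if (result$pev$kernel_kind %in% c("G", "G05", "Gs", "H") && U == 2L) {
        warning("group-ratio r with a genomic-type kernel and two management ",
                "units is unreliable; prefer pair averaging")
      }
      S <- crossprod(Mu, result$pev$pev %*% Mu)
      if (any(diag(S) <= 0)) stop("nonpositive within-block PEV sum",
                                  call. = FALSE)
      S / sqrt(outer(diag(S), diag(S)))
    }
  )
  dimnames(um) <- list(labels, labels)
  diag(um) <- NA_real_
  result$unit_matrix <- um
  result$overall <- mean(um[upper.tri(um)])
  result$summary_mode <- mode
  result$units <- units
  result
}

#' Stratify across-unit connectedness by full-sib linkage
#'
#' Partitions management-unit pairs by whether at least one full-sib
#' pair (same known sire and dam) straddles the two units, and averages
#' the unit-pair statistic within each stratum. In designs where
#' relatedness is concentrated in full-sib families, the with-full-sib
#' stratum is where the genetic links across units live.
#'
#' @param result A summarized `connectedness_result` (run
#'   [summarize_across_units()] first, or pass `units`).
#' @param ped A `pedigree` identifying full-sib pairs.
#' @param units A `unit_assignment`; defaults to the one stored by the
#'   summary step.
#' @return List with `overall_no_fullsib`, `overall_with_fullsib`
#'   (either may be `NA` when its stratum is empty) and the unit-pair
#'   counts `n_no_fullsib`, `n_with_fullsib`.
#' @export
stratify_by_fullsibs <- function(result, ped, units = result$units) {
  if (is.null(result$unit_matrix)) {
    result <- summarize_across_units(result, units)
  }
  lab <- units$unit[match(result$ids, units$id)]
  labels <- rownames(result$unit_matrix)
  fam <- ifelse(!is.na(ped$sire) & !is.na(ped$dam),
                paste(ped$sire, ped$dam, sep = "\r"), NA_character_)
  names(fam) <- ped$id
  fam_of <- fam[result$ids]
  linked <- matrix(FALSE, length(labels), length(labels),
                   dimnames = list(labels, labels))
  for (f in unique(stats::na.omit(fam_of))) {
    u <- unique(lab[!is.na(fam_of) & fam_of == f])
    if (length(u) > 1L) {
      for (a in u) for (b in u) if (a != b) linked[a, b] <- TRUE
    }
  }
  up <- upper.tri(result$unit_matrix)
  vals <- result$unit_matrix[up]
  has_fs <- linked[up]
  list(
    overall_no_fullsib = if (any(!has_fs)) mean(vals[!has_fs]) else NA_real_,
    overall_with_fullsib = if (any(has_fs)) mean(vals[has_fs]) else NA_real_,
    n_no_fullsib = sum(!has_fs),
    n_with_fullsib = sum(has_fs)
  )
}

#' Principal components of a pairwise connectedness matrix
#'
#' Column-centered PCA (no variance scaling, keeping the metric of the
#' statistic) of the individual-by-individual connectedness matrix;
#' returns the first two component scores per individual with
#' explained-variance proportions, for visual assessment of how a
#' kernel or scenario groups or mixes the management units.
#'
#' @param result A `connectedness_result`.
#' @return Data.frame with columns `id`, `PC1`, `PC2`; attribute
#'   `explained` holds the two explained-variance proportions.
#' @export
pca_connectedness <- function(result) {
  m <- result$pairwise
  if (nrow(m) < 3L) stop("need at least 3 individuals for PCA", call. = FALSE)
  if (anyNA(m)) {
    m[is.na(m)] <- mean(m, na.rm = TRUE)   # undefined pairs: neutral fill
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  out <- data.frame(id = result$ids, PC1 = pc$x[, 1], PC2 = pc$x[, 2],
                    row.names = NULL)
  attr(out, "explained") <- ev[1:2]
  out
}
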