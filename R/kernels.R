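#' Relationship kernel matrices
#'
#' A kernel matrix is an n x n symmetric relatedness matrix over a set of
#' individuals, tagged by how it was constructed: `"A"` (expected-IBD
#' numerator relationship from pedigree), `"G"` (VanRaden genomic
#' relationship at observed allele frequencies), `"G05"` (base allele
#' frequencies fixed at one-half), `"Gs"` (min-max rescaling of G to the
#' [0, 2] range of A) or `"H"` (single-step hybrid of pedigree and
#' genomic relationships).
#'
#' @param values Symmetric numeric matrix with individual ids as
#'   dimnames.
#' @param kind One of `"A"`, `"G"`, `"G05"`, `"Gs"`, `"H"`.
#' @param jitter_applied Diagonal jitter added so far (see
#'   [ensure_invertible()]).
#' @return A `kernel_matrix`: the matrix with `kind` and
#'   `jitter_applied` attributes.
#' @export
kernel_matrix <- function(values, kind, jitter_applied = 0) {
  kind <- match.arg(kind, c("A", "G", "G05", "Gs", "H"))
  if (is.null(rownames(values))) {
    stop("kernel matrix needs individual ids as dimnames", call. = FALSE)
  }
  if (max(abs(values - t(values))) > 1e-8 * max(1, max(abs(values)))) {
    stop("kernel matrix is not symmetric", call. = FALSE)
  }
  values <- (values + t(values)) / 2
  structure(values, kind = kind, jitter_applied = jitter_applied,
            class = c("kernel_matrix", "matrix", "array"))
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("<kernel_matrix kind=%s, %d individuals>\n",
              attr(x, "kind"), nrow(x)))
  print(as.matrix(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

kernel_kind <- function(k) attr(k, "kind")

#' Extract the plain relationship matrix from a kernel
#'
#' @param x A `kernel_matrix`.
#' @param ... Unused.
#' @return The underlying numeric matrix without kernel attributes.
#' @export
as.matrix.kernel_matrix <- function(x, ...) {
  v <- unclass(x)
  attr(v, "kind") <- NULL
  attr(v, "jitter_applied") <- NULL
  v
}

#' Numerator relationship matrix from pedigree (tabular method)
#'
#' Computes A, whose entries are twice the kinship coefficients: the
#' expected proportion of alleles identical by descent. Uses the tabular
#' recursion over a topological ordering — a_ii = 1 + 0.5 a(sire, dam)
#' and a_ij = 0.5 (a(j, sire_i) + a(j, dam_i)) — with unknown parents
#' treated as unrelated, non-inbred founders.
#'
#' @param ped A `pedigree`.
#' @return A `kernel_matrix` of kind `"A"` in the pedigree's id order.
#' @export
numerator_relationship <- function(ped) {
  ord <- attr(ped, "topo_order")
  if (is.null(ord)) ord <- pedigree_order(ped)
  n <- nrow(ped)
  ids <- ped$id[ord]
  pos <- seq_len(n); names(pos) <- ids
  sire <- unname(pos[ped$sire[ord]])   # NA when unknown
  dam <- unname(pos[ped$dam[ord]])
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- sire[i]; d <- dam[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + 0.5 * A[s, j]
      if (!is.na(d)) row <- row + 0.5 * A[d, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A <- A[ped$id, ped$id, drop = FALSE]
  kernel_matrix(A, kind = "A")
}

#' VanRaden genomic relationship matrix
#'
#' Standardizes the allele-count matrix column-wise,
#' W_j = (w_j - 2 p_j) / sqrt(2 p_j (1 - p_j)), and returns
#' G = W W' / m. With `freqs = "observed"` the p_j are the observed
#' allele frequencies (kind `"G"`); with `freqs = 0.5` all base
#' frequencies are fixed at one-half (kind `"G05"`), which avoids the
#' negative coefficients that observed-frequency centering produces.
#'
#' @param g A complete `genotype_table` (impute first).
#' @param freqs Either `"observed"` or the constant `0.5`.
#' @return A `kernel_matrix` of kind `"G"` or `"G05"`.
#' @export
vanraden_G <- function(g, freqs = "observed") {
  if (anyNA(g$counts)) {
    stop("genotypes contain missing values; run impute_missing() first",
         call. = FALSE)
  }
  w <- g$counts
  storage.mode(w) <- "double"
  if (identical(freqs, "observed")) {
    p <- g$allele_freqs
    if (any(p <= 0 | p >= 1)) {
      stop("monomorphic marker(s) have zero variance at observed frequencies; ",
           "apply filter_maf() first", call. = FALSE)
    }
    kind <- "G"
  } else if (is.numeric(freqs) && length(freqs) == 1L && freqs == 0.5) {
    p <- rep(0.5, ncol(w))
    kind <- "G05"
  } else {
    stop("freqs must be \"observed\" or the constant 0.5", call. = FALSE)
  }
  W <- sweep(w, 2, 2 * p, "-")
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
  G <- tcrossprod(W) / ncol(W)
  dimnames(G) <- list(g$ids, g$ids)
  kernel_matrix(G, kind = kind)
}

#' Min-max rescaling of a genomic relationship matrix
#'
#' Affinely maps the global minimum and maximum entries of G to `lo` and
#' `hi` (default 0 and 2, the range of the numerator relationship
#' matrix). The map is order-preserving, so the correlation between input
#' and output entries is exactly one, and former negative entries become
#' nonnegative.
#'
#' @param k A `kernel_matrix` of kind `"G"`.
#' @param lo,hi Target range (defaults 0 and 2).
#' @return A `kernel_matrix` of kind `"Gs"`.
#' @export
minmax_scale <- function(k, lo = 0, hi = 2) {
  rng <- range(k)
  if (diff(rng) == 0) {
    stop("constant relationship matrix: min-max range is degenerate",
         call. = FALSE)
  }
  v <- (hi - lo) * (as.matrix(k) - rng[1]) / diff(rng) + lo
  kernel_matrix(v, kind = "Gs")
}

#' Single-step hybrid relationship matrix
#'
#' Combines pedigree relationships over all individuals with genomic
#' relationships over the genotyped subset by conditioning the genetic
#' values of ungenotyped individuals on those of genotyped ones:
#' H11 = A11 + A12 A22^-1 (G22 - A22) A22^-1 A21,
#' H12 = A12 A22^-1 G22, H22 = G22.
#'
#' @param a `kernel_matrix` of kind `"A"` over all individuals.
#' @param g22 Genomic `kernel_matrix` over the genotyped individuals.
#' @param genotyped_ids Character vector of genotyped ids (a subset of
#'   the ids of `a`; must match the ids of `g22`).
#' @return A `kernel_matrix` of kind `"H"` in the id order of `a`.
#' @export
hybrid_H <- function(a, g22, genotyped_ids) {
  ids <- rownames(a)
  if (!all(genotyped_ids %in% ids)) {
    stop("genotyped_ids must be a subset of the pedigree individuals",
         call. = FALSE)
  }
  if (length(genotyped_ids) == 0L) {
    return(kernel_matrix(as.matrix(a), kind = "H"))
  }
  if (!setequal(rownames(g22), genotyped_ids)) {
    stop("g22 must be indexed by exactly the genotyped ids", call. = FALSE)
  }
  G22 <- as.matrix(g22)[genotyped_ids, genotyped_ids, drop = FALSE]
  if (length(genotyped_ids) == length(ids)) {
    return(kernel_matrix(G22[ids, ids, drop = FALSE], kind = "H"))
  }
  ung <- setdiff(ids, genotyped_ids)
  A11 <- as.matrix(a)[ung, ung, drop = FALSE]
  A12 <- as.matrix(a)[ung, genotyped_ids, drop = FALSE]
  A22 <- as.matrix(a)[genotyped_ids, genotyped_ids, drop = FALSE]
  A22inv <- tryCatch(solve(A22), error = function(e) {
    stop("A22 is singular; consider ensure_invertible() on A or a jitter",
         call. = FALSE)
  })
  P <- A12 %*% A22inv                    # n1 x n2 projection
  H11 <- A11 + P %*% (G22 - A22) %*% t(P)
  H12 <- P %*% G22
  H <- rbind(cbind(H11, H12), cbind(t(H12), G22))
  dimnames(H) <- list(c(ung, genotyped_ids), c(ung, genotyped_ids))
  kernel_matrix(H[ids, ids, drop = FALSE], kind = "H")
}

#' Regularize a kernel for inversion
#'
#' Adds `jitter` to the diagonal only if the smallest eigenvalue is below
#' `tol`, recording the amount applied. The genomic relationship matrix
#' is rank-deficient whenever markers are fewer than individuals (or
#' individuals are duplicated), and the mixed model equations need its
#' inverse.
#'
#' @param k A `kernel_matrix`.
#' @param jitter Diagonal increment (default `1e-6 * mean(diag(k))`).
#' @param tol Eigenvalue tolerance below which jitter is applied.
#' @return The (possibly jittered) `kernel_matrix` with
#'   `jitter_applied` updated.
#' @export
ensure_invertible <- function(k, jitter = 1e-6 * mean(diag(k)), tol = 1e-8) {
  ev <- eigen(as.matrix(k), symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev))
  if (min(ev) > tol * scale) return(k)
  v <- as.matrix(k) + diag(jitter, nrow(k))
  ev2 <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev2) <= tol * max(abs(ev2))) {
    stop("kernel still numerically singular after jitter ", jitter,
         call. = FALSE)
  }
  kernel_matrix(v, kind = kernel_kind(k),
                jitter_applied = attr(k, "jitter_applied") + jitter)
}
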