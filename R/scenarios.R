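#' Dissimilarity from a relationship matrix
#'
#' D_ij = max(A) - A_ij, so the most-related pair has distance zero and
#' relatedness maps monotonically to closeness. The diagonal is forced
#' to zero (self-dissimilarity), as k-medoid clustering requires.
#'
#' @param a A symmetric `kernel_matrix` (clustering is done on the
#'   pedigree matrix A).
#' @return Symmetric dissimilarity matrix with zero diagonal.
#' @export
relationship_dissimilarity <- function(a) {
  d <- max(a) - as.matrix(a)
  diag(d) <- 0
  d
}

#' Partitioning around medoids on a precomputed dissimilarity
#'
#' k-medoid clustering: every individual is assigned to its nearest
#' medoid and the total within-cluster dissimilarity is minimized over
#' medoid sets. Small instances (at most `exact_limit` candidate medoid
#' sets) are solved exactly by enumeration — BUILD + SWAP is a local
#' search and can settle on a suboptimal medoid set when the problem is
#' tiny enough that exhaustive search is free. Larger instances use
#' BUILD + SWAP via the cluster package. Both routes are deterministic
#' for a given dissimilarity (ties go to the lowest-index medoid set);
#' the `seed` argument is kept for interface symmetry with the other
#' stochastic steps and does not alter the result.
#'
#' @param d Symmetric dissimilarity matrix with zero diagonal,
#'   individual ids as dimnames.
#' @param k Number of clusters, 2 <= k < n.
#' @param seed Unused placeholder (the solver is deterministic).
#' @param exact_limit Maximum number of medoid subsets enumerated before
#'   falling back to BUILD + SWAP (default 5000).
#' @return A `cluster_solution`: list with `assignments` (named integer
#'   vector), `medoids` (ids), `k`, `avg_silhouette` and the total
#'   within-cluster dissimilarity `objective`.
#' @export
pam_cluster <- function(d, k, seed = NULL, exact_limit = 5000) {
  n <- nrow(d)
  if (k < 2L || k >= n) stop("k must satisfy 2 <= k < n", call. = FALSE)
  ids <- rownames(d)
  if (choose(n, k) <= exact_limit) {
    best <- Inf; med_idx <- NULL
    for (med in utils::combn(n, k, simplify = FALSE)) {
      obj <- sum(apply(d[, med, drop = FALSE], 1, min))
      if (obj < best - 1e-12) { best <- obj; med_idx <- med }
    }
    assignments <- apply(d[, med_idx, drop = FALSE], 1, which.min)
    obj <- best
  } else {
    fit <- cluster::pam(stats::as.dist(d), k = k, do.swap = TRUE)
    med_idx <- fit$id.med
    assignments <- fit$clustering
    obj <- sum(d[cbind(seq_len(n), med_idx[assignments])])
  }
  names(assignments) <- ids
  sil <- cluster::silhouette(assignments, stats::as.dist(d))
  structure(list(assignments = assignments, medoids = ids[med_idx], k = k,
                 avg_silhouette = mean(sil[, "sil_width"]), objective = obj),
            class = "cluster_solution")
}

#' Select the number of clusters by average silhouette width
#'
#' Runs [pam_cluster()] over `k_range` and keeps the solution with the
#' largest average silhouette width s(i) = (b_i - a_i)/max(a_i, b_i);
#' ties go to the smaller k.
#'
#' @param d Dissimilarity matrix as in [pam_cluster()].
#' @param k_range Integer vector of candidate cluster counts (default
#'   2..min(15, n-1)).
#' @param seed Unused placeholder.
#' @return The winning `cluster_solution`; attribute `silhouette_by_k`
#'   holds the profile over `k_range`.
#' @export
choose_k_silhouette <- function(d, k_range = 2:min(15, nrow(d) - 1),
                                seed = NULL) {
  if (!length(k_range)) stop("empty k_range", call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  fits <- lapply(k_range, function(k) pam_cluster(d, k, seed))
  sil <- vapply(fits, `[[`, numeric(1), "avg_silhouette")
  best <- fits[[which.max(sil)]]   # which.max takes the first (smallest k) tie
  attr(best, "silhouette_by_k") <- stats::setNames(sil, k_range)
  best
}

#' Allocate clusters to management units under a designed scenario
#'
#' Emulates four levels of designed connectedness on top of a cluster
#' solution. Clusters are ordered by decreasing size (ties by medoid
#' id); splits balance the number of individuals per unit.
#' \describe{
#'   \item{1 — completely disconnected}{each cluster is its own unit}
#'   \item{2 — disconnected}{consecutive clusters divided into two
#'     units at the cut that best balances individual counts}
#'   \item{3 — partially connected}{first third of clusters to unit 1,
#'     last third to unit 2; individuals of the middle (linking)
#'     clusters split between both units}
#'   \item{4 — connected}{every cluster's individuals split between the
#'     two units, sizes within one}
#' }
#'
#' @param clusters A `cluster_solution`.
#' @param scenario Integer 1-4.
#' @param seed Integer seed for the randomized within-cluster splits
#'   (scenarios 3 and 4).
#' @return A `unit_assignment` covering every clustered individual.
#' @export
assign_scenario <- function(clusters, scenario, seed = 1L) {
  scenario <- as.integer(scenario)
  if (!scenario %in% 1:4) stop("scenario must be 1, 2, 3 or 4", call. = FALSE)
  asg <- clusters$assignments
  sizes <- table(asg)
  ord <- order(-as.integer(sizes), clusters$medoids)  # big first, tie by medoid
  cl_order <- as.integer(names(sizes))[ord]
  if (scenario >= 2L && length(cl_order) < 2L) {
    stop("scenario ", scenario, " needs at least 2 clusters", call. = FALSE)
  }
  if (scenario == 3L && length(cl_order) < 3L) {
    stop("scenario 3 needs at least 3 clusters", call. = FALSE)
  }
  ids <- names(asg)
  unit <- character(length(asg))
  if (scenario == 1L) {
    unit <- paste0("MU", match(asg, cl_order))
  } else if (scenario == 2L) {
    cut <- best_cut(as.integer(sizes)[ord])
    unit <- ifelse(match(asg, cl_order) <= cut, "MU1", "MU2")
  } else if (scenario == 3L) {
    cuts <- best_thirds(as.integer(sizes)[ord])
    pos <- match(asg, cl_order)
    grp <- ifelse(pos <= cuts[1], 1L, ifelse(pos <= cuts[2], 2L, 3L))
    unit[grp == 1L] <- "MU1"
    unit[grp == 3L] <- "MU2"
    link_ids <- ids[grp == 2L]
    unit[grp == 2L] <- balanced_split(link_ids, seed)
  } else {
    for (cl in cl_order) {
      members <- ids[asg == cl]
      unit[asg == cl] <- balanced_split(members, seed + cl)
    }
  }
  as_unit_assignment(data.frame(id = ids, unit = unit))
}

# index after which to cut an ordered size vector into two consecutive
# groups with the most balanced individual totals
best_cut <- function(sizes) {
  tot <- sum(sizes)
  cum <- cumsum(sizes)[seq_len(length(sizes) - 1L)]
  which.min(abs(tot - 2 * cum))
}

# two cut indices making three consecutive, individual-balanced groups
best_thirds <- function(sizes) {
  ncl <- length(sizes)
  tot <- sum(sizes)
  best <- NULL; best_dev <- Inf
  for (c1 in 1:(ncl - 2L)) {
    for (c2 in (c1 + 1L):(ncl - 1L)) {
      g <- c(sum(sizes[1:c1]), sum(sizes[(c1 + 1L):c2]),
             sum(sizes[(c2 + 1L):ncl]))
      dev <- sum((g - tot / 3)^2)
      if (dev < best_dev) { best_dev <- dev; best <- c(c1, c2) }
    }
  }
  best
}

# randomly halve ids into MU1/MU2 with sizes within one
balanced_split <- function(ids, seed) {
  n <- length(ids)
  pick <- with_seed(seed, sample.int(n, n %/% 2))
  out <- rep("MU1", n)
  out[pick] <- "MU2"
  out
}
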