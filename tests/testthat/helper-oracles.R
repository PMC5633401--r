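# Independent oracles and fixture builders. These deliberately avoid the
# code paths they check: kinship by direct memoized recursion, medoid
# search by exhaustive enumeration, quadratic forms by explicit sums.

# Recursive kinship coefficients phi(i, j); A_oracle = 2 * phi.
kinship_oracle <- function(ped) {
  n <- nrow(ped)
  pos <- seq_len(n); names(pos) <- ped$id
  sire <- unname(pos[ped$sire]); dam <- unname(pos[ped$dam])
  memo <- new.env(hash = TRUE)
  phi <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    key <- paste(min(i, j), max(i, j))
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      0.5 * (1 + phi(sire[i], dam[i]))
    } else {
      # recurse on the younger individual (appears later topologically)
      topo <- attr(ped, "topo_order")
      rank <- order(topo)
      if (rank[i] > rank[j]) 0.5 * (phi(sire[i], j) + phi(dam[i], j))
      else 0.5 * (phi(sire[j], i) + phi(dam[j], i))
    }
    memo[[key]] <- val
    val
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in seq_len(i)) {
    A[i, j] <- A[j, i] <- 2 * phi(i, j)
  }
  A
}

# Exhaustive k-medoid search: best objective over all medoid subsets.
brute_medoid_objective <- function(d, k) {
  n <- nrow(d)
  best <- Inf
  for (med in utils::combn(n, k, simplify = FALSE)) {
    obj <- sum(apply(d[, med, drop = FALSE], 1, min))
    best <- min(best, obj)
  }
  best
}

# Random acyclic pedigree: n_founders founders then offspring with
# parents drawn from earlier individuals (both known or both unknown).
random_pedigree <- function(n, n_founders = max(3L, n %/% 3), seed = 1L) {
  set.seed(seed)
  id <- sprintf("I%02d", seq_len(n))
  sire <- rep(NA_character_, n); dam <- rep(NA_character_, n)
  for (i in seq.int(n_founders + 1L, length.out = max(0L, n - n_founders))) {
    par <- sample(i - 1L, 2L)
    sire[i] <- id[par[1]]; dam[i] <- id[par[2]]
  }
  as_pedigree(data.frame(id = id, sire = sire, dam = dam))
}

# Random symmetric dissimilarity with zero diagonal.
random_dissimilarity <- function(n, seed = 1L) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n), n, n)
  d <- (m + t(m)) / 2
  diag(d) <- 0
  dimnames(d) <- list(sprintf("I%02d", 1:n), sprintf("I%02d", 1:n))
  d
}

# Random units over a set of ids, each of n_units units non-empty.
random_units <- function(ids, n_units, seed = 1L) {
  set.seed(seed)
  n <- length(ids)
  lab <- c(seq_len(n_units),
           sample(n_units, n - n_units, replace = TRUE))[sample(n)]
  as_unit_assignment(data.frame(id = ids, unit = paste0("U", lab)))
}

# A random instance for the absorption/full-MME cross-checks: pedigree,
# one of the five kernel kinds over it, and a unit assignment.
random_pev_instance <- function(seed) {
  set.seed(seed)
  n <- sample(8:30, 1)
  ped <- random_pedigree(n, seed = seed + 1L)
  kind <- sample(c("A", "G", "G05", "Gs", "H"), 1)
  k <- if (kind == "A") {
    numerator_relationship(ped)
  } else {
    cfg <- sim_config(n_markers = 60L, seed = seed + 2L)
    geno <- gene_drop_genotypes(ped, cfg)
    geno <- filter_maf(geno, 0.01)
    G <- vanraden_G(geno)
    switch(kind,
      G = G,
      G05 = vanraden_G(geno, 0.5),
      Gs = minmax_scale(G),
      H = {
        gids <- sample(ped$id, max(2L, n %/% 2))
        A <- numerator_relationship(ped)
        g22 <- kernel_matrix(unclass(G)[gids, gids, drop = FALSE], kind = "G")
        hybrid_H(A, g22, gids)
      })
  }
  units <- random_units(ped$id, sample(2:5, 1), seed = seed + 3L)
  list(ped = ped, kernel = k, units = units)
}

expect_symmetric <- function(m, tol = 1e-10) {
  expect_lt(max(abs(m - t(m))), tol)
}
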