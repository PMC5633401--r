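#' Simulation configuration
#'
#' Bundles the knobs of the data generators. The defaults emulate the
#' two study designs the package targets: a heterogeneous-stock-style
#' mouse population of full-sib families reared across shared cages
#' (169 families of ~11 sibs spread over 3 cages each), and a
#' multi-generation dairy-cattle-style pedigree in which only the recent
#' generations are genotyped (six generations totalling 1929 animals,
#' with the last three generations — about 35% of individuals —
#' genotyped).
#'
#' @param n_families Number of full-sib families (mouse design).
#' @param sibs_per_family Full sibs per family.
#' @param cages_per_family Cages over which each family's sibs spread.
#' @param share_fraction Fraction of adjacent family pairs whose cages
#'   are merged, creating units that mix two families (default 0: cages
#'   are single-family, so cross-unit links come only from full sibs of
#'   the same family housed in different cages).
#' @param gen_sizes Individuals per generation, founders first (cattle
#'   design). The default sums to 1929 with the last three generations
#'   holding 35% of individuals.
#' @param n_lines Closed breeding lines in the multi-generation design:
#'   founders are split into lines and mating stays within line, which
#'   plants the cluster-structured relatedness that kinship clustering
#'   is meant to recover (default 8).
#' @param n_generations Number of generations (length of `gen_sizes`).
#' @param offspring_per_mating Offspring produced per sampled
#'   sire-dam pair.
#' @param n_markers Markers for gene dropping.
#' @param founder_maf_range Range of founder minor allele frequencies,
#'   within (0, 0.5].
#' @param h2 Heritability used for phenotype simulation.
#' @param seed Base seed for the generators.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_families = 169L, sibs_per_family = 11L,
                       cages_per_family = 3L, share_fraction = 0,
                       gen_sizes = c(418L, 418L, 418L, 225L, 225L, 225L),
                       n_generations = length(gen_sizes),
                       n_lines = 8L,
                       offspring_per_mating = 1L,
                       n_markers = 10000L,
                       founder_maf_range = c(0.05, 0.5),
                       h2 = 0.8, seed = 1L) {
  cfg <- list(n_families = as.integer(n_families),
              sibs_per_family = as.integer(sibs_per_family),
              cages_per_family = as.integer(cages_per_family),
              share_fraction = share_fraction,
              gen_sizes = as.integer(gen_sizes),
              n_generations = as.integer(n_generations),
              n_lines = as.integer(n_lines),
              offspring_per_mating = as.integer(offspring_per_mating),
              n_markers = as.integer(n_markers),
              founder_maf_range = founder_maf_range,
              h2 = h2, seed = as.integer(seed))
  stopifnot(cfg$n_families >= 1L, cfg$sibs_per_family >= 1L,
            cfg$cages_per_family >= 1L, cfg$n_markers >= 1L,
            cfg$share_fraction >= 0, cfg$share_fraction <= 1,
            length(cfg$gen_sizes) == cfg$n_generations)
  if (cfg$founder_maf_range[1] <= 0 || cfg$founder_maf_range[2] > 0.5 ||
      diff(cfg$founder_maf_range) < 0) {
    stop("founder_maf_range must lie within (0, 0.5]", call. = FALSE)
  }
  if (cfg$h2 <= 0 || cfg$h2 >= 1) stop("h2 must be in (0, 1)", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a full-sib family / cage design
#'
#' Each family consists of two unrelated, non-inbred founder parents and
#' `sibs_per_family` full-sib offspring distributed as evenly as
#' possible over `cages_per_family` cages. Only offspring receive cage
#' (management-unit) assignments — parents are not phenotyped. With the
#' default `share_fraction = 0`, every cage holds a single family, so
#' pedigree relatedness is 0.5 within cages of the same family and 0
#' across families: connectedness across units is carried entirely by
#' full sibs housed in different cages. A positive `share_fraction`
#' merges the last cage of selected families with the first cage of the
#' next family, creating two-family units.
#'
#' @param cfg A `sim_config`.
#' @return List with `ped` (a `pedigree` of parents and offspring) and
#'   `units` (a `unit_assignment` over the offspring).
#' @export
simulate_mice_design <- function(cfg) {
  if (cfg$sibs_per_family < cfg$cages_per_family) {
    stop("sibs_per_family must be >= cages_per_family", call. = FALSE)
  }
  nf <- cfg$n_families
  rows <- vector("list", nf)
  unit_rows <- vector("list", nf)
  for (f in seq_len(nf)) {
    sire <- sprintf("F%03d_S", f); dam <- sprintf("F%03d_D", f)
    kids <- sprintf("F%03d_O%02d", f, seq_len(cfg$sibs_per_family))
    cage <- sprintf("F%03d_C%d", f,
                    rep_len(seq_len(cfg$cages_per_family), length(kids)))
    rows[[f]] <- data.frame(
      id = c(sire, dam, kids),
      sire = c(NA, NA, rep(sire, length(kids))),
      dam = c(NA, NA, rep(dam, length(kids))))
    unit_rows[[f]] <- data.frame(id = kids, unit = cage)
  }
  units <- do.call(rbind, unit_rows)
  if (cfg$share_fraction > 0 && nf > 1L) {
    n_share <- round(cfg$share_fraction * (nf - 1L))
    shared <- with_seed(cfg$seed, sort(sample.int(nf - 1L, n_share)))
    for (f in shared) {
      from <- sprintf("F%03d_C%d", f, cfg$cages_per_family)
      to <- sprintf("F%03d_C1", f + 1L)
      units$unit[units$unit == from] <- to
    }
  }
  list(ped = as_pedigree(do.call(rbind, rows)),
       units = as_unit_assignment(units))
}

#' Simulate a discrete-generation pedigree with a genotyped recent subset
#'
#' Generation 0 holds unrelated founders split into `n_lines` closed
#' breeding lines; each later generation is bred by random mating of
#' distinct sire-dam pairs within line (`offspring_per_mating` offspring
#' per sampled pair), so relatedness accumulates within lines and stays
#' zero across them — the cluster structure that kinship-based
#' clustering is meant to recover. Individuals in the most recent
#' `ceiling(n_generations / 2)` generations form the genotyped subset,
#' mirroring breeding programs where genotyping concentrates in recent
#' animals.
#'
#' @param cfg A `sim_config`.
#' @return List with `ped` (a `pedigree`; attributes `generation` and
#'   `line` map id to generation number and breeding line) and
#'   `genotyped_ids`.
#' @export
simulate_cattle_design <- function(cfg) {
  gs <- cfg$gen_sizes
  if (length(gs) < 2L) stop("need at least 2 generations", call. = FALSE)
  n_lines <- max(1L, cfg$n_lines)
  if (gs[1] < 2L * n_lines) {
    stop("too few founders for distinct sire-dam pairs in every line",
         call. = FALSE)
  }
  with_seed(cfg$seed + 1L, {
    ids <- sprintf("G0_%04d", seq_len(gs[1]))
    ped <- data.frame(id = ids, sire = NA_character_, dam = NA_character_)
    gen <- rep(0L, gs[1])
    line <- rep_len(seq_len(n_lines), gs[1])
    prev <- split(ids, factor(line[seq_len(gs[1])], levels = seq_len(n_lines)))
    for (g in seq_len(length(gs) - 1L)) {
      # line quotas for this generation, sizes within one
      quota <- tabulate(rep_len(seq_len(n_lines), gs[g + 1L]), n_lines)
      if (any(quota < 2L)) {
        stop("generation size ", gs[g + 1L], " too small to keep ", n_lines,
             " lines breedable (need >= 2 per line)", call. = FALSE)
      }
      kids <- character(0); sires <- character(0); dams <- character(0)
      kid_line <- integer(0)
      for (l in seq_len(n_lines)) {
        made <- 0L
        while (made < quota[l]) {
          pair <- sample(prev[[l]], 2L)
          nk <- min(cfg$offspring_per_mating, quota[l] - made)
          kid <- sprintf("G%d_L%d_%03d", g, l, made + seq_len(nk))
          kids <- c(kids, kid)
          sires <- c(sires, rep(pair[1], nk))
          dams <- c(dams, rep(pair[2], nk))
          kid_line <- c(kid_line, rep(l, nk))
          made <- made + nk
        }
      }
      ped <- rbind(ped, data.frame(id = kids, sire = sires, dam = dams))
      gen <- c(gen, rep(g, length(kids)))
      line <- c(line, kid_line)
      prev <- split(kids, factor(kid_line, levels = seq_len(n_lines)))
    }
    ped <- as_pedigree(ped)
    names(gen) <- ped$id
    names(line) <- ped$id
    attr(ped, "generation") <- gen
    attr(ped, "line") <- line
    recent <- length(gs) - ceiling(length(gs) / 2)   # first genotyped gen
    list(ped = ped, genotyped_ids = ped$id[gen >= recent])
  })
}

#' Gene-drop genotypes down a pedigree
#'
#' Founders draw two alleles per marker from Bernoulli(p_j), where p_j
#' is sampled uniformly from the configured founder MAF range and
#' mirrored to the upper half of the frequency spectrum with probability
#' one-half. Non-founders inherit one uniformly chosen allele from each
#' parent per marker, independently across markers (no linkage). Under
#' this Mendelian transmission the expected genomic relationship equals
#' the pedigree relationship, which is what makes the generator a
#' testable oracle for the kernel pipeline. Individuals must have both
#' parents known or both unknown.
#'
#' @param ped A `pedigree`.
#' @param cfg A `sim_config` (uses `n_markers`, `founder_maf_range`,
#'   `seed`).
#' @return A complete `genotype_table` over the pedigree's individuals.
#' @export
gene_drop_genotypes <- function(ped, cfg) {
  one_parent <- xor(is.na(ped$sire), is.na(ped$dam))
  if (any(one_parent)) {
    stop("gene dropping requires both parents known or both unknown; ",
         "offending id(s): ",
         paste(utils::head(ped$id[one_parent], 5), collapse = ", "),
         call. = FALSE)
  }
  ord <- attr(ped, "topo_order")
  n <- nrow(ped); m <- cfg$n_markers
  pos <- seq_len(n); names(pos) <- ped$id
  with_seed(cfg$seed + 2L, {
    q <- stats::runif(m, cfg$founder_maf_range[1], cfg$founder_maf_range[2])
    flip <- stats::runif(m) < 0.5
    p <- ifelse(flip, 1 - q, q)
    a1 <- matrix(0L, n, m); a2 <- matrix(0L, n, m)
    for (i in ord) {
      s <- pos[ped$sire[i]]; d <- pos[ped$dam[i]]
      if (is.na(s)) {
        a1[i, ] <- stats::rbinom(m, 1L, p)
        a2[i, ] <- stats::rbinom(m, 1L, p)
      } else {
        from1 <- stats::runif(m) < 0.5
        a1[i, ] <- ifelse(from1, a1[s, ], a2[s, ])
        from2 <- stats::runif(m) < 0.5
        a2[i, ] <- ifelse(from2, a1[d, ], a2[d, ])
      }
    }
    counts <- a1 + a2
    dimnames(counts) <- list(ped$id, sprintf("M%05d", seq_len(m)))
    as_genotype_table(counts)
  })
}

#' Simulate phenotypes under the animal model
#'
#' Draws genetic values u with covariance K h2, adds a management-unit
#' effect (sd `unit_effect_sd`) and residuals with variance 1 - h2, and
#' standardizes y to mean 0, variance 1. Phenotype values never enter
#' the prediction-error machinery — this exists for end-to-end
#' demonstrations of the model the statistics assume.
#'
#' @param k A positive semi-definite `kernel_matrix`.
#' @param units A `unit_assignment` over (a subset of) the kernel's ids.
#' @param h2 Heritability in (0, 1).
#' @param unit_effect_sd Standard deviation of unit effects before
#'   standardization (default 0.3).
#' @param seed Integer seed.
#' @return Data.frame with columns `id`, `unit`, `y`.
#' @export
simulate_phenotypes <- function(k, units, h2, unit_effect_sd = 0.3, seed = 1L) {
  if (h2 <= 0 || h2 >= 1) stop("h2 must be in (0, 1)", call. = FALSE)
  km <- as.matrix(align_kernel(k, units$id))
  ev <- eigen(km, symmetric = TRUE)
  if (min(ev$values) < -1e-6 * max(abs(ev$values))) {
    stop("kernel is not positive semi-definite", call. = FALSE)
  }
  lam <- pmax(ev$values, 0)
  with_seed(seed + 3L, {
    u <- drop(ev$vectors %*% (sqrt(lam * h2) * stats::rnorm(length(lam))))
    b <- stats::rnorm(length(unique(units$unit)), 0, unit_effect_sd)
    names(b) <- unique(units$unit)
    y <- u + b[units$unit] + stats::rnorm(nrow(units), 0, sqrt(1 - h2))
    data.frame(id = units$id, unit = units$unit,
               y = as.numeric(scale(y)), row.names = NULL)
  })
}
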