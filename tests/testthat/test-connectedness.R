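# Shared small fixture: two full-sib families, two cages each, so both
# connected (within-family) and disconnected (across-family) unit pairs
# exist.
fixture_design <- function(h2 = 0.8, kernel = c("A", "G")) {
  kernel <- match.arg(kernel)
  cfg <- sim_config(n_families = 4L, sibs_per_family = 6L,
                    cages_per_family = 2L, n_markers = 400L, seed = 31)
  md <- simulate_mice_design(cfg)
  k <- if (kernel == "A") numerator_relationship(md$ped)
       else vanraden_G(filter_maf(gene_drop_genotypes(md$ped, cfg), 0.01))
  des <- build_design(md$units)
  vm <- variance_model_from_h2(h2)
  list(md = md, k = k, pev = pev_absorption(des, k, vm), vm = vm)
}

test_that("PEVD is zero on the diagonal and invariant to variance scale", {
  fx <- fixture_design()
  pe <- pevd_pairwise(fx$pev)
  expect_equal(unname(diag(pe$pairwise)), rep(0, length(fx$pev$ids)))
  expect_symmetric(pe$pairwise)

  # scaled PEVD depends on the components only through lambda
  des <- build_design(fx$md$units)
  p_small <- pev_absorption(des, fx$k, variance_model(0.8, 0.2))
  p_big <- pev_absorption(des, fx$k, variance_model(8, 2))
  expect_equal(pevd_pairwise(p_small)$pairwise, pevd_pairwise(p_big)$pairwise,
               tolerance = 1e-10)
})

test_that("CD uses the relatedness-difference denominator and its limits", {
  # two unrelated individuals in one unit, identity kernel: denominator 2
  ids <- c("a", "b")
  ua <- as_unit_assignment(data.frame(id = ids, unit = c("u", "u")))
  K <- kernel_matrix(diag(2) |> `dimnames<-`(list(ids, ids)), "A")
  vm <- variance_model_from_h2(0.5)
  p <- pev_absorption(build_design(ua), K, vm)
  cd <- suppressWarnings(cd_pairwise(p, K))
  manual <- 1 - vm$lambda *
    (p$c22["a", "a"] + p$c22["b", "b"] - 2 * p$c22["a", "b"]) / 2
  expect_equal(cd$pairwise["a", "b"], manual)

  # lambda -> 0 (h2 -> 1): every defined pair approaches CD = 1
  p1 <- pev_absorption(build_design(ua), K, variance_model(1, 1e-8))
  cd1 <- suppressWarnings(cd_pairwise(p1, K))
  expect_equal(cd1$pairwise["a", "b"], 1, tolerance = 1e-6)

  # self-pairs are undefined
  expect_true(all(is.na(diag(cd$pairwise))))
})

test_that("CD flags pairs with identical relatedness rows", {
  ids <- letters[1:3]
  K <- matrix(0.4, 3, 3, dimnames = list(ids, ids))
  diag(K) <- 1
  K[1, 2] <- K[2, 1] <- 1   # duplicates: K_aa + K_bb - 2 K_ab = 0
  K <- kernel_matrix(K, "G")
  ua <- as_unit_assignment(data.frame(id = ids, unit = c("u1", "u1", "u2")))
  p <- pev_absorption(build_design(ua), K, variance_model_from_h2(0.5))
  expect_warning(cd <- cd_pairwise(p, K), "denominator")
  expect_true(is.na(cd$pairwise["a", "b"]))
  expect_false(is.na(cd$pairwise["a", "c"]))
})

test_that("r is a correlation: unit diagonal, bounded, zero without PEC", {
  fx <- fixture_design()
  r <- r_pairwise(fx$pev)
  expect_equal(unname(diag(r$pairwise)), rep(1, length(fx$pev$ids)))
  expect_true(all(abs(r$pairwise) <= 1 + 1e-12))

  # disconnected units under the identity kernel: r exactly zero
  ids <- letters[1:4]
  ua <- as_unit_assignment(data.frame(id = ids, unit = c("u1", "u1", "u2", "u2")))
  K <- kernel_matrix(diag(4) |> `dimnames<-`(list(ids, ids)), "A")
  p <- pev_absorption(build_design(ua), K, variance_model_from_h2(0.5))
  r0 <- r_pairwise(p)
  expect_equal(r0$pairwise["a", "c"], 0)
  expect_equal(r0$pairwise["b", "d"], 0)
})

test_that("contrast vectors weight unit means and sum to zero", {
  ua <- as_unit_assignment(data.frame(id = letters[1:4],
                                      unit = c("u1", "u1", "u2", "u2")))
  x <- contrast_vector(ua, "u1", "u2")
  expect_equal(unname(x), c(0.5, 0.5, -0.5, -0.5))
  expect_equal(sum(x), 0)

  ub <- as_unit_assignment(data.frame(id = letters[1:4],
                                      unit = c("u1", "u2", "u2", "u2")))
  expect_equal(unname(contrast_vector(ub, "u1", "u2")),
               c(1, -1 / 3, -1 / 3, -1 / 3))
  expect_error(contrast_vector(ua, "u1", "u1"), "distinct")
  expect_error(contrast_vector(ua, "u1", "zz"), "unknown unit")
})

test_that("contrast PEVD reduces to pairwise entries and block sums", {
  fx <- fixture_design()
  pe <- pevd_pairwise(fx$pev)
  expect_equal(pevd_contrast(fx$pev, numeric(length(fx$pev$ids)) |>
                               stats::setNames(fx$pev$ids)), 0)

  # singleton units: the contrast form is the pairwise entry
  ids <- fx$pev$ids[1:2]
  ua <- as_unit_assignment(data.frame(id = fx$pev$ids,
                                      unit = c("s1", "s2",
                                               rep("rest", length(fx$pev$ids) - 2))))
  x <- contrast_vector(ua, "s1", "s2", ids = fx$pev$ids)
  expect_equal(pevd_contrast(fx$pev, x), pe$pairwise[ids[1], ids[2]],
               tolerance = 1e-12)

  # quadratic-form expansion oracle over two arbitrary blocks
  lab <- fx$md$units$unit
  u <- unique(lab)[1:2]
  bi <- fx$pev$ids[lab == u[1]]; bj <- fx$pev$ids[lab == u[2]]
  x2 <- contrast_vector(fx$md$units, u[1], u[2], ids = fx$pev$ids)
  pev <- fx$pev$pev
  manual <- sum(pev[bi, bi]) / length(bi)^2 + sum(pev[bj, bj]) / length(bj)^2 -
    2 * sum(pev[bi, bj]) / (length(bi) * length(bj))
  expect_equal(pevd_contrast(fx$pev, x2),
               manual / fx$vm$sigma_u2, tolerance = 1e-12)
})

test_that("contrast CD reduces to pairwise entries and never exceeds one", {
  fx <- fixture_design()
  cd <- suppressWarnings(cd_pairwise(fx$pev, fx$k))
  ids <- fx$pev$ids
  ua <- as_unit_assignment(data.frame(id = ids,
                                      unit = c("s1", "s2",
                                               rep("rest", length(ids) - 2))))
  x <- contrast_vector(ua, "s1", "s2", ids = ids)
  expect_equal(cd_contrast(fx$pev, fx$k, x), cd$pairwise[ids[1], ids[2]],
               tolerance = 1e-12)

  for (u2 in unique(fx$md$units$unit)[-1]) {
    x <- contrast_vector(fx$md$units, fx$md$units$unit[1], u2, ids = ids)
    expect_lte(cd_contrast(fx$pev, fx$k, x), 1)
  }
  expect_error(cd_contrast(fx$pev, fx$k,
                           numeric(length(ids)) |> stats::setNames(ids)),
               "zero kernel variance")
})

test_that("group-ratio r collapses to the pairwise entry for singletons", {
  fx <- fixture_design()
  ids <- fx$pev$ids
  r <- r_pairwise(fx$pev)
  ua <- as_unit_assignment(data.frame(id = ids,
                                      unit = c("s1", "s2",
                                               rep("rest", length(ids) - 2))))
  expect_equal(r_group_summary(fx$pev, ua, "s1", "s2"),
               r$pairwise[ids[1], ids[2]], tolerance = 1e-12)
})

test_that("group-ratio r warns for genomic kernels with two units", {
  fx <- fixture_design(kernel = "G")
  lab <- fx$md$units$unit
  two <- as_unit_assignment(data.frame(
    id = fx$pev$ids,
    unit = ifelse(lab %in% unique(lab)[1:4], "MU1", "MU2")))
  expect_warning(r_group_summary(fx$pev, two, "MU1", "MU2"), "two management")
  # no warning for the pedigree kernel
  fa <- fixture_design(kernel = "A")
  expect_silent(r_group_summary(fa$pev, two, "MU1", "MU2"))
})

test_that("across-unit summaries average distinct unit pairs", {
  fx <- fixture_design()
  pe <- summarize_across_units(pevd_pairwise(fx$pev), fx$md$units)
  expect_equal(pe$summary_mode, "contrast")
  U <- length(unique(fx$md$units$unit))
  expect_equal(dim(pe$unit_matrix), c(U, U))
  um <- pe$unit_matrix
  diag(um) <- 0
  expect_symmetric(um)
  expect_equal(pe$overall, mean(pe$unit_matrix[upper.tri(pe$unit_matrix)]))

  r <- summarize_across_units(r_pairwise(fx$pev), fx$md$units)
  expect_equal(r$summary_mode, "pair_average")

  # two units: the overall equals the single off-diagonal entry
  lab <- fx$md$units$unit
  two <- as_unit_assignment(data.frame(
    id = fx$pev$ids, unit = ifelse(lab %in% unique(lab)[1:4], "MU1", "MU2")))
  pe2 <- summarize_across_units(pevd_pairwise(fx$pev), two)
  expect_equal(pe2$overall, pe2$unit_matrix["MU1", "MU2"])
})

test_that("summaries are invariant to individual order and unit labels", {
  fx <- fixture_design()
  base <- summarize_across_units(pevd_pairwise(fx$pev), fx$md$units)$overall
  perm <- sample(nrow(fx$md$units))
  ua_perm <- as_unit_assignment(as.data.frame(fx$md$units)[perm, ])
  expect_equal(summarize_across_units(pevd_pairwise(fx$pev), ua_perm)$overall,
               base, tolerance = 1e-12)
  relab <- fx$md$units
  relab$unit <- paste0("zzz_", relab$unit)
  expect_equal(
    summarize_across_units(pevd_pairwise(fx$pev),
                           as_unit_assignment(relab))$overall,
    base, tolerance = 1e-12)
})

test_that("pair-average and group-ratio r agree for singleton units", {
  ped <- random_pedigree(8, seed = 23)
  A <- numerator_relationship(ped)
  ua <- as_unit_assignment(data.frame(id = ped$id,
                                      unit = paste0("u", seq_along(ped$id))))
  p <- pev_absorption(build_design(ua), A, variance_model_from_h2(0.5))
  r <- r_pairwise(p)
  pa <- summarize_across_units(r, ua, mode = "pair_average")
  gr <- summarize_across_units(r, ua, mode = "group_ratio")
  expect_equal(pa$unit_matrix, gr$unit_matrix, tolerance = 1e-12)
})

test_that("identity-kernel baseline: disconnected cross-unit statistics", {
  ids <- letters[1:6]
  ua <- as_unit_assignment(data.frame(id = ids, unit = rep(c("u1", "u2"),
                                                           each = 3)))
  K <- kernel_matrix(diag(6) |> `dimnames<-`(list(ids, ids)), "A")
  vm <- variance_model_from_h2(0.5)
  p <- pev_absorption(build_design(ua), K, vm)
  # cross-unit PEVD = lambda (C22_ii + C22_jj), PEC = 0, r = 0
  pe <- pevd_pairwise(p)
  expect_equal(pe$pairwise["a", "d"],
               vm$lambda * (p$c22["a", "a"] + p$c22["d", "d"]))
  expect_equal(p$pev["a", "d"], 0)
  expect_equal(r_pairwise(p)$pairwise["a", "d"], 0)
  # within-unit pairs carry information the cross-unit pairs lack
  cd <- suppressWarnings(cd_pairwise(p, K))
  expect_gt(cd$pairwise["a", "b"], cd$pairwise["a", "d"])
})

test_that("full-sib stratification partitions unit pairs", {
  fx <- fixture_design()
  pe <- summarize_across_units(pevd_pairwise(fx$pev), fx$md$units)
  st <- stratify_by_fullsibs(pe, fx$md$ped, fx$md$units)
  U <- length(unique(fx$md$units$unit))
  expect_equal(st$n_no_fullsib + st$n_with_fullsib, choose(U, 2))
  # 4 families x 2 cages: exactly one full-sib-linked pair per family
  expect_equal(st$n_with_fullsib, 4L)
  # full sibs across cages connect; unrelated families do not
  expect_lt(st$overall_with_fullsib, st$overall_no_fullsib)
  # the two strata average back to the overall
  expect_equal((st$overall_no_fullsib * st$n_no_fullsib +
                  st$overall_with_fullsib * st$n_with_fullsib) / choose(U, 2),
               pe$overall)

  # every unit pair full-sib linked -> empty no-full-sib stratum
  lab <- fx$md$units$unit
  fam <- substr(fx$md$units$id, 1, 4)
  one_fam <- as_unit_assignment(data.frame(
    id = fx$md$units$id[fam == "F001"],
    unit = lab[fam == "F001"]))
  pe1 <- summarize_across_units(
    pevd_pairwise(pev_absorption(build_design(one_fam), fx$k,
                                 variance_model_from_h2(0.8))), one_fam)
  st1 <- stratify_by_fullsibs(pe1, fx$md$ped, one_fam)
  expect_equal(st1$n_no_fullsib, 0L)
  expect_true(is.na(st1$overall_no_fullsib))
})

test_that("moving a full sib across units strengthens connectedness", {
  # two disconnected families in two cages each; swapping one sib of
  # family 1 into a family-2 cage creates a genetic link
  cfg <- sim_config(n_families = 2L, sibs_per_family = 5L,
                    cages_per_family = 2L, n_markers = 100L, seed = 37)
  md <- simulate_mice_design(cfg)
  A <- numerator_relationship(md$ped)
  vm <- variance_model_from_h2(0.8)
  before <- summarize_across_units(
    pevd_pairwise(pev_absorption(build_design(md$units), A, vm)), md$units)
  moved <- md$units
  moved$unit[match("F001_O01", moved$id)] <- "F002_C1"
  moved <- as_unit_assignment(moved)
  after <- summarize_across_units(
    pevd_pairwise(pev_absorption(build_design(moved), A, vm)), moved)
  expect_lt(after$overall, before$overall)
})

test_that("connectedness PCA separates blocks and handles duplicates", {
  fx <- fixture_design()
  r <- r_pairwise(fx$pev)
  sc <- pca_connectedness(r)
  expect_equal(nrow(sc), length(fx$pev$ids))
  expect_lte(sum(attr(sc, "explained")), 1)

  # exact duplicate rows get identical scores
  m <- r$pairwise
  m[2, ] <- m[1, ]; m[, 2] <- m[, 1]; m[2, 2] <- m[1, 1]
  r2 <- r
  r2$pairwise <- m
  sc2 <- pca_connectedness(r2)
  expect_equal(sc2[1, c("PC1", "PC2")], sc2[2, c("PC1", "PC2")],
               ignore_attr = TRUE, tolerance = 1e-8)

  # block-diagonal structure: PC1 splits the blocks
  ids <- sprintf("i%02d", 1:10)
  bm <- matrix(0, 10, 10, dimnames = list(ids, ids))
  bm[1:5, 1:5] <- 0.8; bm[6:10, 6:10] <- 0.8
  diag(bm) <- 1
  rb <- r
  rb$pairwise <- bm
  rb$ids <- ids
  scb <- pca_connectedness(rb)
  expect_true(all(sign(scb$PC1[1:5]) == sign(scb$PC1[1])))
  expect_true(all(sign(scb$PC1[6:10]) == -sign(scb$PC1[1])))

  small <- r
  small$pairwise <- m[1:2, 1:2]
  small$ids <- fx$pev$ids[1:2]
  expect_error(pca_connectedness(small), "at least 3")
})
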