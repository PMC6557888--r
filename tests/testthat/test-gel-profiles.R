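# Master-gel construction, replicate selection, HMG/CHMG comparison and
# excisable-spot selection.

three_identical_reps <- function(n = 10, morph = "W") {
  set.seed(99)
  base <- make_spots(pI = runif(n, 3, 10), log10_mw = runif(n, 1, 1.6),
                     morph = morph)
  lapply(1:3, function(r) { base$replicate <- r; base })
}

test_that("identical replicates yield a master with full support", {
  reps <- three_identical_reps(10)
  mg <- match_replicates(reps)
  expect_equal(nrow(mg$spots), 10)
  expect_true(all(mg$spots$support == 3))
  expect_setequal(mg$spots$spot_id, reps[[1]]$spot_id)
})

test_that("a spot present in a single replicate is excluded from the master", {
  reps <- three_identical_reps(8)
  lone <- make_spots(pI = 5.5, log10_mw = 1.2, ids = "lonely", replicate = 1)
  reps[[1]] <- rbind(reps[[1]], lone)
  mg <- match_replicates(reps)
  expect_false("lonely" %in% mg$spots$spot_id)
  expect_equal(nrow(mg$spots), 8)
})

test_that("match_replicates validates its inputs", {
  reps <- three_identical_reps(5)
  expect_error(match_replicates(reps[1:2]), "3 replicates")
  mixed <- reps; mixed[[2]]$morph <- "Y"
  expect_error(match_replicates(mixed), "mix morphs")
})

test_that("replicate selection drops the worst of four and passes three through", {
  reps4 <- c(three_identical_reps(10), list(NULL))
  clean <- reps4[[1]]; clean$replicate <- 4
  reps4[[4]] <- clean
  # four identical replicates: tie, the largest replicate id is dropped
  out <- select_best_replicates(reps4)
  expect_equal(vapply(out, function(r) unique(r$replicate), numeric(1)),
               1:3)
  # a heavily speckled replicate is dropped
  set.seed(7)
  speckled <- make_spots(pI = runif(30, 3, 10),
                         log10_mw = runif(30, 1, 1.6),
                         ids = sprintf("spk%02d", 1:30), replicate = 2)
  reps4[[2]] <- speckled
  out <- select_best_replicates(reps4)
  expect_false(2 %in% vapply(out, function(r) unique(r$replicate),
                             numeric(1)))
  expect_identical(select_best_replicates(reps4[c(1, 3, 4)]),
                   reps4[c(1, 3, 4)])
  expect_error(select_best_replicates(reps4[1:2]), "4 replicates")
})

test_that("HMG summary applies the mean/sum denominator conventions", {
  expect_equal(summarize_hmg(10, 20, 20),
               c(pct_common = 50, pct_unique_a = 25, pct_unique_b = 25))
  expect_error(summarize_hmg(21, 20, 25), "exceeds")
  expect_error(summarize_hmg(-1, 20, 25), "non-negative")
})

test_that("comparing a master gel with a copy of itself finds all spots common", {
  reps <- three_identical_reps(9, morph = "W")
  a <- match_replicates(reps)
  b <- a; b$morph <- "Y"
  h <- compare_master_gels(a, b)
  expect_equal(h$common, 9)
  expect_equal(h$unique_a, 0)
  expect_equal(h$unique_b, 0)
  expect_equal(h$pct_common, 100)
  expect_error(compare_master_gels(a, a), "distinct morphs")
})

test_that("disjoint master gels share no spots and matching is symmetric", {
  mk <- function(pI, morph) {
    structure(list(morph = morph,
                   spots = make_spots(pI = pI,
                                      log10_mw = rep(1.2, length(pI)),
                                      ids = sprintf("%s%02d", morph,
                                                    seq_along(pI)),
                                      morph = morph)),
              class = "master_gel")
  }
  a <- mk(c(3, 4, 5), "W"); b <- mk(c(7, 8, 9, 9.5), "Y")
  h <- compare_master_gels(a, b)
  expect_equal(h$common, 0)
  expect_equal(h$unique_a, 3); expect_equal(h$unique_b, 4)
  # symmetry on an overlapping fixture
  set.seed(21)
  a <- mk(runif(8, 3, 10), "W"); b <- mk(runif(8, 3, 10), "Y")
  b$spots$pI[1:4] <- a$spots$pI[1:4] + 0.03
  b$spots$log10_mw[1:4] <- a$spots$log10_mw[1:4] + 0.005
  hab <- compare_master_gels(a, b); hba <- compare_master_gels(b, a)
  expect_equal(hab$common, hba$common)
  expect_equal(hab$unique_a, hba$unique_b)
  expect_setequal(paste(hab$pairs$id_a, hab$pairs$id_b),
                  paste(hba$pairs$id_b, hba$pairs$id_a))
  # count identities
  expect_equal(hab$common + hab$unique_a, hab$n_a)
  expect_equal(hab$common + hab$unique_b, hab$n_b)
})

test_that("mutual-nearest matching equals exhaustive assignment on small fixtures", {
  for (seed in 1:100) {
    set.seed(seed)
    na <- sample(3:12, 1); nb <- sample(3:12, 1)
    a <- make_spots(pI = runif(na, 3, 10), log10_mw = runif(na, 1, 1.6),
                    ids = sprintf("a%02d", 1:na))
    b <- make_spots(pI = a$pI[seq_len(min(na, nb))] + rnorm(min(na, nb),
                                                            0, 0.05),
                    log10_mw = a$log10_mw[seq_len(min(na, nb))] +
                      rnorm(min(na, nb), 0, 0.01),
                    ids = sprintf("b%02d", seq_len(min(na, nb))))
    got <- match_spots(a, b)
    want <- oracle_match(a, b)
    expect_equal(nrow(got), want$count, info = paste("seed", seed))
    expect_equal(sum(got$dist), want$cost, tolerance = 1e-9,
                 info = paste("seed", seed))
  }
})

test_that("master size is monotone non-increasing as tolerances shrink", {
  cfg <- generator_config()
  truth <- simulate_proteomes(cfg, 13)
  gels <- simulate_gels(truth, cfg, 13)
  g <- gels[gels$morph == "W", ]
  reps <- select_best_replicates(unname(split(g, g$replicate)))
  sizes <- vapply(c(1, 0.5, 0.25, 0.1),
                  function(f) nrow(match_replicates(reps, 0.1 * f,
                                                    0.02 * f)$spots),
                  integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("masters recover the truth manifest and admit no speckles", {
  cfg <- generator_config()
  truth <- simulate_proteomes(cfg, 1)
  gels <- simulate_gels(truth, cfg, 1)
  recovered <- logical(0)
  for (m in c("W", "Y", "R")) {
    g <- gels[gels$morph == m, ]
    reps <- select_best_replicates(unname(split(g, g$replicate)))
    mg <- match_replicates(reps)
    truth_ids <- names(truth$spot_protein)[
      startsWith(names(truth$spot_protein), paste0(m, ":"))]
    recovered <- c(recovered, truth_ids %in% mg$spots$spot_id)
    expect_equal(sum(startsWith(mg$spots$spot_id, "speckle_")), 0)
  }
  expect_gte(mean(recovered), 0.95)
})

test_that("common HMG pairs map to shared truth proteins on synthetic data", {
  cfg <- generator_config()
  truth <- simulate_proteomes(cfg, 2)
  gels <- simulate_gels(truth, cfg, 2)
  masters <- lapply(setNames(c("W", "Y"), c("W", "Y")), function(m) {
    g <- gels[gels$morph == m, ]
    match_replicates(select_best_replicates(unname(split(g, g$replicate))))
  })
  h <- compare_master_gels(masters$W, masters$Y)
  acc_a <- truth$spot_protein[h$pairs$id_a]
  acc_b <- truth$spot_protein[h$pairs$id_b]
  ok <- !is.na(acc_a) & !is.na(acc_b)
  # at least 90% of matched pairs join the two morphs' spots of one protein
  expect_gte(mean(acc_a[ok] == acc_b[ok]), 0.9)
})

test_that("CHMG labels partition spots and match the truth flags", {
  cfg <- generator_config()
  truth <- simulate_proteomes(cfg, 3)
  gels <- simulate_gels(truth, cfg, 3)
  masters <- lapply(setNames(c("W", "Y", "R"), c("W", "Y", "R")),
                    function(m) {
    g <- gels[gels$morph == m, ]
    match_replicates(select_best_replicates(unname(split(g, g$replicate))))
  })
  ch <- combine_hmgs(compare_master_gels(masters$W, masters$Y),
                     compare_master_gels(masters$W, masters$R),
                     compare_master_gels(masters$Y, masters$R))
  expect_true(all(ch$spots$label %in%
                    c("shared", "unique_W", "unique_Y", "unique_R")))
  # CHMG-unique spots should overwhelmingly carry truth-unique proteins
  uniq <- ch$spots[ch$spots$label != "shared", ]
  flags <- truth$unique_flags[uniq$spot_id]
  ok <- !is.na(flags)
  expect_gte(mean(flags[ok] == sub("unique_", "", uniq$label[ok])), 0.85)
  expect_error(combine_hmgs(compare_master_gels(masters$W, masters$Y),
                            compare_master_gels(masters$W, masters$Y),
                            compare_master_gels(masters$Y, masters$R)),
               "cover morph pairs")
})

test_that("excisable selection respects the separation rule", {
  sp <- data.frame(
    spot_id = c("u1", "u2", "s1", "u3", "u4"),
    morph = c("W", "Y", "W", "R", "R"),
    pI = c(3, 5, 7, 9, 9.001),
    log10_mw = c(1.2, 1.2, 1.2, 1.2, 1.2),
    intensity = c(5, 4, 3, 2, 1),
    label = c("unique_W", "unique_Y", "shared", "unique_R", "unique_R"))
  ch <- structure(list(spots = sp), class = "chmg")
  # all far apart: every unique spot excisable; coincident pair excluded
  expect_equal(select_excisable(ch, 0.05), c("u1", "u2"))
  sp$pI <- c(3, 5, 7, 9, 11)
  ch <- structure(list(spots = sp), class = "chmg")
  expect_equal(select_excisable(ch, 0.05), c("u1", "u2", "u3", "u4"))
})
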