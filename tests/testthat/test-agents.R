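mk <- function(...) b_cell_clone("t1", 1e-8, ...)

test_that("clone construction and derived quantities", {
  cl <- b_cell_clone("c1", 1e-8, apparent_factor = 10, n_cells = 4,
                     bcr_per_cell = 1e5)
  expect_equal(kd_intrinsic(cl), 1e-8)
  expect_equal(kd_apparent(cl), 1e-9)
  expect_equal(paratope_count(cl), 4e5)
  llpc <- b_cell_clone("c2", 1e-9, stage = "LLPC")
  expect_identical(paratope_count(llpc), 0) # terminal cells lose the BCR
  expect_error(b_cell_clone("c3", 0), "> 0")
  expect_error(b_cell_clone("c3", 1e-9, apparent_factor = 0), "apparent_factor")
  expect_error(b_cell_clone("c3", 1e-9, stage = "NOT_A_STAGE"))
})

test_that("decide_fate implements the fate machine on its anchor cases", {
  fol <- mk(stage = "FOLLICULAR_BII")
  expect_identical(decide_fate(fol, "COMFORT", "FOLLICLE", FALSE)$action,
                   "REST_G0")
  pre <- mk(stage = "SMALL_PRE_BII", edit_attempts_left = 2)
  expect_identical(decide_fate(pre, "UNDER", "BONE_MARROW")$action,
                   "EDIT_RECEPTOR")
  spent <- mk(stage = "SMALL_PRE_BII", edit_attempts_left = 0)
  expect_identical(decide_fate(spent, "UNDER", "BONE_MARROW")$action, "DIE")
  imm <- mk(stage = "IMMATURE")
  # clonal deletion of aggressive self-binders
  expect_identical(decide_fate(imm, "SATURATED", "BONE_MARROW", TRUE)$action,
                   "DIE")
  expect_identical(decide_fate(imm, "NEGLECT", "BONE_MARROW")$action, "DIE")
  expect_identical(decide_fate(fol, "OVER", "FOLLICLE", TRUE)$action,
                   "ENTER_GC")
  expect_identical(decide_fate(fol, "OVER", "FOLLICLE", FALSE)$action,
                   "DIVIDE")
})

test_that("decide_fate is total over the configured state machine", {
  for (stage in bcrsim:::B_CELL_STAGES) {
    for (eng in bcrsim:::ENGAGEMENT_LEVELS) {
      for (nk in bcrsim:::NICHE_KINDS) {
        for (second in c(FALSE, TRUE)) {
          cl <- mk(stage = stage)
          fa <- decide_fate(cl, eng, nk, second)
          expect_s3_class(fa, "fate_action")
          expect_true(fa$action %in% bcrsim:::FATE_ACTIONS)
        }
      }
    }
  }
  # unknown labels raise configuration errors, never a silent default
  expect_error(decide_fate(mk(), "WHATEVER", "BLOOD"), "engagement")
  expect_error(decide_fate(mk(), "COMFORT", "SPLEEN"), "niche")
})

test_that("divide_clone doubles and clamps at the population cap", {
  expect_equal(divide_clone(mk(n_cells = 1))$n_cells, 2)
  expect_equal(divide_clone(mk(n_cells = 64))$n_cells, 128)
  expect_equal(divide_clone(mk(n_cells = 3), mode = "increment")$n_cells, 4)
  expect_warning(capped <- divide_clone(mk(n_cells = 2^20)), "cap")
  expect_equal(capped$n_cells, 2^20)
  expect_warning(clamped <- divide_clone(mk(n_cells = 2^20 - 10)), "cap")
  expect_equal(clamped$n_cells, 2^20)
})

test_that("receptor editing resamples within germline bounds and spends budget", {
  cl <- mk(stage = "SMALL_PRE_BII", edit_attempts_left = 3,
           mut_h = 2, mut_l = 1)
  set.seed(21)
  ed <- receptor_edit(cl)
  expect_equal(ed$edit_attempts_left, 2L)
  expect_identical(ed$mut_h, 0L)
  expect_identical(ed$mut_l, 0L)
  # replay determinism
  set.seed(21)
  expect_identical(receptor_edit(cl)$log10_kd, ed$log10_kd)
  # empirical sampler bounds over many resamples
  set.seed(22)
  kds <- replicate(1e4, kd_intrinsic(receptor_edit(cl)))
  expect_true(all(kds >= 1e-10 & kds <= 1e-6))
  # spanning the range, not stuck at a corner
  expect_lt(min(kds), 1e-9)
  expect_gt(max(kds), 1e-7)
  spent <- mk(edit_attempts_left = 0)
  expect_error(receptor_edit(spent), "no editing attempts")
})

test_that("isotype switch raises apparent affinity only", {
  cl <- b_cell_clone("s1", 1e-6, isotype = "IgM")
  sw <- isotype_switch(cl, "IgG", switch_gain = 10)
  expect_identical(sw$isotype, "IgG")
  expect_equal(kd_apparent(sw), 1e-7)
  expect_equal(kd_intrinsic(sw), 1e-6)
  expect_equal(kd_apparent(isotype_switch(cl, "IgA", switch_gain = 1)), 1e-6)
  expect_warning(again <- isotype_switch(sw, "IgA"), "already switched")
  expect_identical(again$isotype, "IgG")
  expect_equal(kd_apparent(again), 1e-7)
})

test_that("shm_mutate respects caps, chains and the deleterious bias", {
  shm <- shm_params()
  capped <- mk(stage = "GC_B", mut_h = 30, mut_l = 20)
  expect_identical(shm_mutate(capped, shm), capped)
  expect_error(shm_mutate(mk(stage = "MEMORY"), shm), "GC_B")
  # replay determinism of the whole draw sequence
  cl <- mk(stage = "GC_B")
  set.seed(31)
  a <- replicate(50, {
    r <- shm_mutate(cl, shm)
    if (is.null(r)) NA_real_ else r$log10_kd
  })
  set.seed(31)
  b <- replicate(50, {
    r <- shm_mutate(cl, shm)
    if (is.null(r)) NA_real_ else r$log10_kd
  })
  expect_identical(a, b)
  # law of large numbers on the configured rates; the deleterious probability
  # renormalized over viable outcomes is p_del / (1 - p_lethal) = 5/7
  set.seed(32)
  n <- 2e4
  res <- replicate(n, {
    r <- shm_mutate(cl, shm)
    if (is.null(r)) NA else r$log10_kd > cl$log10_kd
  })
  p_lethal_hat <- mean(is.na(res))
  expect_lt(abs(p_lethal_hat - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  del <- res[!is.na(res)]
  p_del_expected <- 0.5 / 0.7
  se <- sqrt(p_del_expected * (1 - p_del_expected) / length(del))
  expect_lt(abs(mean(del) - p_del_expected), 3 * se)
})

test_that("mutation counters never exceed caps under any horizon", {
  shm <- shm_params()
  set.seed(33)
  cl <- mk(stage = "GC_B")
  for (i in 1:500) {
    nxt <- shm_mutate(cl, shm)
    if (!is.null(nxt)) cl <- nxt
    expect_lte(cl$mut_h, 30L)
    expect_lte(cl$mut_l, 20L)
  }
  # after 500 events both counters have hit their caps
  expect_identical(cl$mut_h, 30L)
  expect_identical(cl$mut_l, 20L)
  # a single-chain cap reroutes mutation to the other chain
  hcap <- mk(stage = "GC_B", mut_h = 30, mut_l = 0)
  set.seed(34)
  for (i in 1:50) {
    nxt <- shm_mutate(hcap, shm_params(p_lethal = 0))
    expect_identical(nxt$mut_h, 30L)
    expect_gt(nxt$mut_l, hcap$mut_l)
    hcap <- mk(stage = "GC_B", mut_h = 30, mut_l = min(nxt$mut_l, 19L))
  }
})

test_that("classify_blood_fate maps the over-engagement bands", {
  band <- engagement_band()
  imm <- mk(stage = "IMMATURE")
  expect_identical(classify_blood_fate(imm, "NEGLECT", FALSE, -Inf, band)$action,
                   "DIE")
  expect_identical(classify_blood_fate(imm, "COMFORT", FALSE, 0.1, band)$action,
                   "REST_G0")
  # moderate over-engagement inside (delta_comfort, delta_b1]: the B1 fate
  b1 <- classify_blood_fate(imm, "OVER", FALSE, 1.0, band)
  expect_identical(b1$action, "PERSIST_G1")
  expect_identical(b1$new_stage, "B1")
  # strong over-engagement with second signal: marginal-zone fate, apparent
  # affinity damped until the log-ratio is back inside the comfort band
  mz <- classify_blood_fate(imm, "SATURATED", TRUE, 3.0, band)
  expect_identical(mz$new_stage, "MZB")
  adj <- apply_fate_differentiation(imm, mz)
  post_ratio <- 3.0 + log10(kd_apparent(imm) / kd_apparent(adj))
  expect_lte(abs(post_ratio), band$delta_comfort)
  # strong over-engagement without help: primary TI expansion
  expect_identical(classify_blood_fate(imm, "OVER", FALSE, 3.0, band)$action,
                   "DIVIDE")
  expect_error(classify_blood_fate(mk(stage = "B1"), "OVER", FALSE, 1, band),
               "IMMATURE")
})
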