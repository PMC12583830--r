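test_that("a flat library shows no enrichment anywhere", {
  # identical raw scores: the boundary tie rule pulls everyone into the top
  # set, so every fold is exactly the trivial ratio 1 and nothing is called
  ref <- protein_seq(paste(rep(AA_ALPHABET, 2), collapse = ""))
  m <- uniform_matrix(ref$residues)
  lib <- rank_and_normalize(scan_single_mutants(m))
  en <- class_enrichment(lib, top_fraction = 0.05)
  expect_equal(en$fold_enrichment, rep(1, nrow(en)))
  # Welch t undefined on constant scores: reported NA, never significant
  expect_true(all(is.na(en$p_value)))
  expect_false(any(!is.na(en$p_adjusted) & en$p_adjusted < 0.05))
})

test_that("a planted class bias is detected and agrees with a permutation oracle", {
  m <- gen_fitness_matrix(L = 80, class_bias = c(K = 2.0), seed = 31)
  lib <- rank_and_normalize(scan_single_mutants(m))
  en <- class_enrichment(lib, top_fraction = 0.05)
  expect_equal(en$class[1], "K")           # largest fold enrichment
  expect_lt(en$p_adjusted[en$class == "K"], 0.05)
  expect_lt(en$p_hyper_adjusted[en$class == "K"], 0.05)

  # direction check against a permutation oracle on the mean-score gap
  is_k <- lib$mt == "K"
  obs <- mean(lib$raw_score[is_k]) - mean(lib$raw_score[!is_k])
  perm <- withr::with_seed(17, vapply(1:500, function(i) {
    sh <- sample(lib$raw_score)
    mean(sh[is_k]) - mean(sh[!is_k])
  }, numeric(1)))
  expect_gt(obs, 0)
  expect_lt(mean(abs(perm) >= abs(obs)), 0.05)
})

test_that("enrichment needs multiple classes and a ranked single-mutant library", {
  lib <- data.frame(variant = "A1K", mt = "K", raw_score = 1, rank = 1)
  expect_error(class_enrichment(lib), class = "fitscan_error_invalid_library")
  expect_error(class_enrichment(data.frame(x = 1)),
               class = "fitscan_error_invalid_library")
})

test_that("fold enrichment is invariant to monotone score rescaling", {
  m <- gen_fitness_matrix(L = 40, class_bias = c(W = 1.5), seed = 8)
  lib <- rank_and_normalize(scan_single_mutants(m))
  en1 <- class_enrichment(lib, 0.05)
  lib2 <- lib
  lib2$raw_score <- exp(lib2$raw_score / 2)   # strictly increasing
  lib2 <- rank_and_normalize(lib2[, setdiff(names(lib2), c("rank", "normalized_score"))])
  en2 <- class_enrichment(lib2, 0.05)
  expect_equal(stats::setNames(en2$fold_enrichment, en2$class)[en1$class],
               stats::setNames(en1$fold_enrichment, en1$class))
})

test_that("quota selection fills the study quotas exactly when pools allow", {
  m <- gen_fitness_matrix(L = 300, seed = 12)
  lib <- rank_and_normalize(scan_single_mutants(m))
  quotas <- c(K = 6, C = 3, W = 3, M = 3, R = 3)
  sel <- quota_select(lib, quotas, top_fraction = 0.05)
  expect_equal(nrow(sel), 18L)
  expect_equal(length(attr(sel, "underfilled")), 0L)
  expect_equal(anyDuplicated(sel$variant), 0L)
  expect_false(is.unsorted(sel$rank))
  counts <- table(sel$mt)
  expect_equal(as.integer(counts[names(quotas)]), unname(as.integer(quotas)))
})

test_that("empty quotas select nothing; shortfalls are reported not fatal", {
  m <- gen_fitness_matrix(L = 40, seed = 4)
  lib <- rank_and_normalize(scan_single_mutants(m))
  expect_equal(nrow(quota_select(lib, stats::setNames(numeric(), character()))), 0L)
  # demand more K mutants than the tiny top pool can hold
  sel <- quota_select(lib, c(K = 500), top_fraction = 0.05)
  expect_lt(nrow(sel), 500L)
  expect_equal(unname(attr(sel, "underfilled")["K"]), 500 - nrow(sel))
})

test_that("quota selection equals a brute-force filter-and-sort oracle", {
  lib <- rank_and_normalize(data.frame(
    variant = paste0("A", 1:10, c("K", "K", "R", "K", "R", "C", "K", "R", "C", "W")),
    pos = 1:10, wt = "A",
    mt = c("K", "K", "R", "K", "R", "C", "K", "R", "C", "W"),
    raw_score = c(5, 4.5, 4, 3.5, 3, 2.5, 2, 1.5, 1, 0.5)))
  sel <- quota_select(lib, c(K = 2, R = 1), pool = "all")
  oracle <- rbind(utils::head(lib[lib$mt == "K", ], 2),
                  utils::head(lib[lib$mt == "R", ], 1))
  oracle <- oracle[order(oracle$rank), ]
  expect_equal(sel$variant, oracle$variant)
})

test_that("dedup keeps the measured-efficiency winner per position", {
  # the study's eight positives collapse to the five-mutation background set
  cand <- data.frame(
    variant = c("G1218R", "T622W", "V1015K", "G1218K", "C80K", "C80M", "C80R", "C574K"),
    pos = c(1218, 622, 1015, 1218, 80, 80, 80, 574),
    wt = c("G", "T", "V", "G", "C", "C", "C", "C"),
    mt = c("R", "W", "K", "K", "K", "M", "R", "K"),
    raw_score = c(3, 2, 2, 2.8, 2.5, 2.6, 2.4, 1.9),
    efficiency = c(1.64, 1.10, 1.05, 1.30, 1.25, 1.20, 1.11, 1.02))
  kept <- dedup_positions(cand, priority = "efficiency")
  expect_equal(kept$variant, c("C80K", "C574K", "T622W", "V1015K", "G1218R"))
})

test_that("dedup leaves conflict-free input unchanged and demands priorities", {
  cand <- data.frame(variant = c("A1K", "C2W"), pos = c(1, 2),
                     wt = c("A", "C"), mt = c("K", "W"),
                     raw_score = c(1, 2))
  expect_equal(dedup_positions(cand)$variant, cand$variant)

  cand2 <- data.frame(variant = c("A1K", "A1W"), pos = c(1, 1),
                      wt = "A", mt = c("K", "W"),
                      raw_score = c(1, 2), efficiency = c(NA, 1))
  expect_error(dedup_positions(cand2, priority = "efficiency"),
               class = "fitscan_error_missing_priority")
})

test_that("dedup output matches a group-by-position oracle on random sets", {
  withr::with_seed(77, {
    for (i in 1:20) {
      n <- sample(5:25, 1)
      pos <- sample(1:8, n, replace = TRUE)
      mt <- sample(AA_ALPHABET, n, replace = TRUE)
      cand <- data.frame(variant = paste0("A", pos, mt), pos = pos,
                         wt = "A", mt = mt, raw_score = rnorm(n))
      cand <- cand[!duplicated(paste(cand$pos, cand$mt)), ]
      kept <- dedup_positions(cand)
      expect_equal(sort(unique(cand$pos)), kept$pos)
      for (j in seq_len(nrow(kept))) {
        grp <- cand[cand$pos == kept$pos[j], ]
        expect_equal(kept$raw_score[j], max(grp$raw_score))
      }
    }
  })
})

test_that("selection plans round-trip through YAML and JSON", {
  plan <- list(top_fraction = 0.05,
               quotas = list(K = 6, C = 3, W = 3, M = 3, R = 3))
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(plan, yml)
  got <- read_selection_plan(yml)
  expect_equal(got$top_fraction, 0.05)
  expect_equal(got$quotas, c(K = 6, C = 3, W = 3, M = 3, R = 3))

  jsn <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(plan, jsn, auto_unbox = TRUE)
  expect_equal(read_selection_plan(jsn)$quotas, got$quotas)
})
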