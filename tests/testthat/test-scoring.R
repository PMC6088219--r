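test_that("GHQ-12 bimodal scoring recodes 0-0-1-1 and sums", {
  expect_identical(score_ghq12(rep(0L, 12)), 0L)
  expect_identical(score_ghq12(rep(3L, 12)), 12L)
  expect_identical(score_ghq12(c(3, 3, 2, 2, 1, 1, 0, 0, 3, 2, 1, 0)), 6L)
  # likert mode is the plain sum
  expect_identical(score_ghq12(rep(3L, 12), method = "likert"), 36L)
  expect_error(score_ghq12(c(rep(0L, 11), 4L)), "item 12")
  expect_error(score_ghq12(rep(0L, 11)), "12 items")
})

test_that("GHQ-12 score is monotone nondecreasing in every item", {
  set.seed(1)
  for (rep in 1:25) {
    items <- sample(0:3, 12, replace = TRUE)
    s0 <- score_ghq12(items)
    i <- sample(12, 1)
    if (items[i] < 3) {
      items[i] <- items[i] + 1L
      expect_gte(score_ghq12(items), s0)
    }
  }
})

test_that("HADS subscale sums items and flags disorder at the cutoff", {
  expect_equal(score_hads(rep(0L, 7)), list(score = 0L, disorder_flag = FALSE))
  expect_equal(score_hads(rep(3L, 7)), list(score = 21L, disorder_flag = TRUE))
  r <- score_hads(c(2, 2, 1, 1, 1, 1, 0))
  expect_identical(r$score, 8L)
  expect_true(r$disorder_flag)
  expect_error(score_hads(rep(1L, 6)), "7 items")
})

test_that("HADS flag equals score >= 8 across a random item-vector sample", {
  set.seed(42)
  for (rep in 1:200) {
    items <- sample(0:3, 7, replace = TRUE)
    r <- score_hads(items)
    expect_identical(r$disorder_flag, sum(items) >= 8)  # oracle: direct sum
  }
})

test_that("SLE domain scores are item means on the 0-5 scale", {
  cb <- sle_codebook()
  expect_identical(vapply(cb, length, integer(1)),
                   c(home_life = 7L, financial = 5L, social_relations = 4L,
                     personal_conflict = 5L, job_conflicts = 4L,
                     educational = 4L, job_security = 5L,
                     loss_separation = 4L, sexual_life = 4L,
                     daily_life = 2L, health_concerns = 2L))
  x <- integer(46)
  expect_equal(unname(score_sle_domains(x)), rep(0, 11))
  x[cb$daily_life] <- 5L
  expect_equal(score_sle_domains(x)[["daily_life"]], 5)
  x2 <- integer(46)
  x2[cb$home_life] <- c(3, 0, 0, 1, 2, 0, 1)
  expect_equal(score_sle_domains(x2)[["home_life"]], 1)
  expect_equal(score_sle_domains(x2, aggregate = "sum")[["home_life"]], 7)
})

test_that("SLE domain scores are invariant to item order within a domain", {
  set.seed(7)
  cb <- sle_codebook()
  items <- sample(0:5, 46, replace = TRUE)
  base <- score_sle_domains(items)
  perm <- items
  perm[cb$financial] <- rev(perm[cb$financial])
  perm[cb$job_security] <- sample(perm[cb$job_security])
  expect_equal(score_sle_domains(perm), base)
})

test_that("SLE scorer rejects a codebook that is not a partition", {
  bad <- sle_codebook()
  bad$daily_life <- bad$health_concerns
  items <- integer(46)
  expect_error(score_sle_domains(items, codebook = bad), "partition")
})

test_that("ERI ratio is the corrected effort/reward quotient", {
  expect_equal(score_eri(rep(2, 6), rep(2, 11)), 1)
  # effort sum 12, reward sum 22 -> 12 / (22 * 6/11) = 1
  expect_equal(score_eri(c(2, 2, 2, 2, 2, 2), c(rep(2, 11)) * 0 + 2), 1)
  expect_equal(score_eri(rep(3, 6), rep(2, 11)), 1.5)
  expect_equal(score_eri(rep(1, 6), rep(1, 11)), 1)
  expect_error(score_eri(rep(0, 6), rep(1, 11)), "strictly positive")
})

test_that("ERI ratio is scale-free under joint scaling", {
  set.seed(3)
  e <- runif(6, 1, 4); r <- runif(11, 1, 4)
  for (c in c(0.5, 2, 10)) {
    expect_equal(score_eri(c * e, c * r), score_eri(e, r))
  }
})

test_that("IPAQ total is the sum of its MET components", {
  expect_equal(score_ipaq(0, 0, 0), 0)
  expect_equal(score_ipaq(8, 4, 3.3), 15.3)
  expect_equal(score_ipaq(12.5, 0, 0), 12.5)
  expect_error(score_ipaq(-1, 0, 0), "nonnegative")
})

test_that("the JSON codebook round-trips and validates", {
  path <- system.file("extdata", "codebook_example.json",
                      package = "quantsem")
  cb <- read_codebook(path)
  expect_length(cb$ghq12, 12)
  expect_length(cb$sle, 46)
  expect_length(cb$eri_effort, 6)
  expect_length(cb$eri_reward, 11)
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(ghq12 = cb$ghq12), bad, auto_unbox = TRUE)
  expect_error(read_codebook(bad), "missing entries")
})

test_that("a raw questionnaire CSV is scored through the pipeline", {
  path <- system.file("extdata", "codebook_example.json",
                      package = "quantsem")
  cb <- read_codebook(path)
  set.seed(19)
  n <- 8L
  raw <- data.frame(matrix(NA, n, 0))
  for (col in cb$ghq12) raw[[col]] <- sample(0:3, n, TRUE)
  for (col in c(cb$hads_anxiety, cb$hads_depression)) {
    raw[[col]] <- sample(0:3, n, TRUE)
  }
  for (col in cb$sle) raw[[col]] <- sample(0:5, n, TRUE)
  for (col in cb$eri_effort) raw[[col]] <- sample(1:4, n, TRUE)
  for (col in cb$eri_reward) raw[[col]] <- sample(1:4, n, TRUE)
  for (col in cb$ipaq) raw[[col]] <- round(runif(n, 0, 20), 1)
  raw$age <- round(rnorm(n, 36, 7))
  for (cv in setdiff(unlist(cb$covariates), "age")) raw[[cv]] <- 1
  csv <- tempfile(fileext = ".csv")
  write.csv(raw, csv, row.names = FALSE)

  out <- file.path(tempdir(), "qsem-raw-score")
  unlink(out, recursive = TRUE)
  res <- suppressWarnings(run_pipeline(list(
    out_dir = out, seed = 2, raw_csv = csv, codebook = path,
    stages = "score")))
  expect_true(file.exists(file.path(out, "scored.csv")))
  expect_identical(nrow(res$scored), n)
  expect_true(all(res$scored$ghq12_distress >= 0 &
                    res$scored$ghq12_distress <= 12))
  expect_true(all(res$scored$hads_anxiety <= 21))
  expect_true(all(res$scored$eri_ratio > 0))
  # hand-check one participant against the item scorers
  i <- 3
  expect_equal(res$scored$ghq12_distress[i],
               score_ghq12(as.integer(raw[i, cb$ghq12])),
               ignore_attr = TRUE)
  expect_equal(res$scored$home_life[i],
               score_sle_domains(as.integer(raw[i, cb$sle]))[["home_life"]])
})

test_that("participant scorer imputes light missingness and flags heavy", {
  cb <- list(
    ghq12 = paste0("g", 1:12),
    hads_anxiety = paste0("ha", 1:7),
    hads_depression = paste0("hd", 1:7),
    sle = paste0("s", 1:46),
    eri_effort = paste0("ee", 1:6),
    eri_reward = paste0("er", 1:11),
    ipaq = paste0("ip", 1:3),
    covariates = list(age = "age")
  )
  set.seed(11)
  n <- 6
  raw <- as.data.frame(matrix(1L, n, 92))
  names(raw) <- c(cb$ghq12, cb$hads_anxiety, cb$hads_depression, cb$sle,
                  cb$eri_effort, cb$eri_reward, cb$ipaq)
  raw$age <- 30:35
  raw$g1[2] <- NA                      # light: imputed
  raw[3, 1:20] <- NA                   # heavy: > 10% of 92 items
  out <- score_participants(raw, cb)
  expect_false(out$excluded[1])
  expect_false(out$excluded[2])
  expect_true(out$excluded[3])
  expect_true(is.na(out$ghq12_distress[3]))
  # row 2: g1 imputed with the rounded instrument mean (1) -> same score
  expect_identical(out$ghq12_distress[2], out$ghq12_distress[1])
  expect_equal(out$age, 30:35)
  expect_equal(out$missing_fraction[1], 0)
})
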