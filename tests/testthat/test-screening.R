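good_profile <- function(...) {
  p <- list(caco2 = -4.5, f20 = 0.1, pgp_sub = 0.2, pgp_inh = 0.1, vd = 1,
            t_half = 0.2, fdamdd = 0.2, sas = 3, logp = 2, logs = -2)
  utils::modifyList(p, list(...))
}

test_that("affinity filter enforces potency and hERG safety strictly", {
  panel <- data.frame(
    DAT = c(-10, -10, -9.54, -10), NET = c(-10, -10, -10, -10),
    SERT = c(-10, -10, -10, -10), hERG = c(-7, -9, -7, -8.18))
  expect_equal(affinity_filter(panel), c(TRUE, FALSE, FALSE, FALSE))
  expect_error(affinity_filter(panel[, -4]), class = "sgnc_data_error")
})

test_that("Lipinski boundaries are inclusive", {
  mols <- data.frame(mw = c(300.140, 500, 500.01),
                     logp = c(4.464, 5, 1),
                     nhd = c(0, 5, 1), nha = c(2, 10, 2))
  flags <- lipinski_filter(mols)
  expect_equal(flags$pass, c(TRUE, TRUE, FALSE))
  expect_false(flags$mw_ok[3])
  expect_true(all(flags$logp_ok))
})

test_that("property classification follows the range table", {
  v <- classify_properties(good_profile())
  expect_true(v$overall_pass)
  expect_equal(v$pct_excellent, 100)
  # medium band and its boundaries: 0.3 is excellent, 0.7 still medium
  expect_equal(classify_properties(good_profile(f20 = 0.5))$classes[["f20"]],
               "medium")
  expect_equal(classify_properties(good_profile(f20 = 0.3))$classes[["f20"]],
               "excellent")
  expect_equal(classify_properties(good_profile(f20 = 0.7))$classes[["f20"]],
               "medium")
  # a property without a medium range fails outright outside excellent
  v2 <- classify_properties(good_profile(sas = 7))
  expect_equal(v2$classes[["sas"]], "fail")
  expect_false(v2$overall_pass)
  expect_equal(v2$pct_excellent, 90)
  # strict one-sided bound at the printed endpoint
  expect_equal(classify_properties(good_profile(sas = 6))$classes[["sas"]],
               "fail")
  expect_equal(classify_properties(good_profile(caco2 = -5.15))$classes[["caco2"]],
               "fail")
  expect_error(classify_properties(good_profile()[-2]),
               class = "sgnc_data_error")
})

test_that("classification agrees with an independent classifier on random profiles", {
  set.seed(18)
  for (i in 1:200) {
    p <- list(caco2 = runif(1, -7, -4), f20 = runif(1), pgp_sub = runif(1),
              pgp_inh = runif(1), vd = runif(1, -1, 25),
              t_half = runif(1), fdamdd = runif(1), sas = runif(1, 1, 8),
              logp = runif(1, -1, 5), logs = runif(1, -6, 1))
    expect_equal(classify_properties(p)$classes, brute_classify(p))
  }
})

test_that("classification is monotone as a value improves class region", {
  rank_of <- c(fail = 0, medium = 1, excellent = 2)
  cls_at <- function(x) {
    classify_properties(good_profile(f20 = x))$classes[["f20"]]
  }
  path <- vapply(c(0.9, 0.5, 0.1), cls_at, character(1))
  expect_true(all(diff(rank_of[path]) >= 1))
})

test_that("novelty filter rejects near-duplicates of references", {
  refs <- reference_set(rbind(c(1, 0, 0), c(0, 1, 0)))
  cands <- rbind(c(1, 0, 0),        # equals a reference
                 c(0, 0, 1),        # orthogonal to both
                 c(0.6, 0.6, 0.0))  # similar to both
  expect_equal(novelty_filter(cands, refs), c(FALSE, TRUE, FALSE))
  set.seed(19)
  cands2 <- matrix(rnorm(50 * 3), 50)
  got <- novelty_filter(cands2, refs, max_sim = 0.4)
  manual <- vapply(seq_len(50), function(i) {
    all(vapply(1:2, function(k) brute_cosine(cands2[i, ], refs$vectors[k, ]),
               numeric(1)) < 0.4)
  }, logical(1))
  expect_equal(got, manual)
})

test_that("lead ranking orders passers by percent excellent then id", {
  v <- data.frame(id = c("b", "a", "c", "d"),
                  overall_pass = c(TRUE, TRUE, TRUE, FALSE),
                  pct_excellent = c(50, 30, 50, 100))
  ranked <- rank_leads(v)
  expect_equal(ranked$id, c("b", "c", "a"))
  none <- rank_leads(v[v$id == "d", ])
  expect_equal(nrow(none), 0L)
  # matches an independent stable sort on a synthetic batch
  set.seed(20)
  v2 <- data.frame(id = sprintf("L%02d", 1:50),
                   overall_pass = sample(c(TRUE, FALSE), 50, replace = TRUE),
                   pct_excellent = sample(seq(0, 100, 10), 50, replace = TRUE))
  ranked2 <- rank_leads(v2)
  keep <- v2[v2$overall_pass, ]
  manual <- keep[order(-keep$pct_excellent, keep$id), ]
  expect_equal(ranked2$id, manual$id)
})

test_that("filter composition is order-independent", {
  spec <- synthetic_spec(n_per_target = 30L, seed = 55)
  fx <- make_codebook_fixture(spec)
  set.seed(56)
  n <- nrow(fx$molecules)
  panel <- data.frame(id = fx$molecules$id,
                      DAT = rnorm(n, -9.6, 1), NET = rnorm(n, -9.6, 1),
                      SERT = rnorm(n, -9.6, 1), hERG = rnorm(n, -8, 1))
  masks <- list(
    affinity = affinity_filter(panel),
    novelty = novelty_filter(fx$latents, fx$refs, max_sim = 0.9),
    lipinski = lipinski_filter(fx$molecules)$pass,
    screening = screen_profiles(fx$profiles)$overall_pass)
  ids <- fx$molecules$id
  survivors <- function(ord) {
    keep <- rep(TRUE, n)
    for (m in ord) keep <- keep & masks[[m]]
    ids[keep]
  }
  base <- survivors(names(masks))
  for (perm in list(c(4, 3, 2, 1), c(2, 4, 1, 3), c(3, 1, 4, 2))) {
    expect_identical(survivors(names(masks)[perm]), base)
  }
  # and equals the brute-force conjunction
  expect_identical(base, ids[Reduce(`&`, masks)])
})
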