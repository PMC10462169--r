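test_that("cosine similarity matches direct arithmetic and its symmetries", {
  expect_equal(cosine_similarity(c(2, 3), c(2, 3)), 1.0)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0.0)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 1 / sqrt(2))
  set.seed(14)
  u <- rnorm(6); v <- rnorm(6)
  expect_equal(cosine_similarity(u, v), cosine_similarity(v, u))
  expect_equal(cosine_similarity(u, 3.7 * v), cosine_similarity(u, v))
  expect_equal(cosine_similarity(u, -2 * v), -cosine_similarity(u, v))
  expect_error(cosine_similarity(u, rep(0, 6)), class = "sgnc_domain_error")
})

test_that("average similarity excludes the candidate and matches a loop", {
  expect_error(avg_similarity(c(1, 1), rbind(c(1, 1))),
               class = "sgnc_domain_error")
  # two members with similarities 0.2 and 0.6 average to 0.4
  cand <- c(1, 0)
  mk <- function(s) c(s, sqrt(1 - s^2))
  expect_equal(avg_similarity(cand, rbind(mk(0.2), mk(0.6))), 0.4)
  set.seed(15)
  dataset <- matrix(rnorm(30 * 5), 30)
  cand <- rnorm(5)
  manual <- mean(vapply(seq_len(30),
                        function(i) brute_cosine(cand, dataset[i, ]),
                        numeric(1)))
  expect_equal(avg_similarity(cand, dataset), manual, tolerance = 1e-12)
})

test_that("count_above uses a strict threshold and matches a filter scan", {
  set.seed(16)
  dataset <- matrix(rnorm(40 * 4), 40)
  cand <- rnorm(4)
  expect_equal(count_above(cand, dataset, 1.0), 0L)
  expect_equal(count_above(cand, dataset, -1.0), 40L)
  sims <- vapply(seq_len(40), function(i) brute_cosine(cand, dataset[i, ]),
                 numeric(1))
  for (th in c(-0.5, 0, 0.3, 0.7)) {
    expect_equal(count_above(cand, dataset, th), sum(sims > th))
  }
})

test_that("reference selection applies the three criteria strictly", {
  # two tight clusters so average similarities are controlled
  set.seed(17)
  base <- c(5, rep(0, 7))
  n <- 12
  z <- sweep(matrix(rnorm(n * 8, sd = 0.2), n), 2L, base, "+")
  mols <- data.frame(
    id = sprintf("R%02d", 1:n), smiles = rep("CC", n), target = "DAT",
    delta_g = rep(-12, n), mw = rep(300, n), logp = rep(2, n),
    nhd = rep(1, n), nha = rep(2, n), stringsAsFactors = FALSE)
  # boundary affinity is excluded (strict "less than")
  mols$delta_g[1] <- -9.54
  # single-criterion Lipinski failures
  mols$mw[2] <- 500.01
  mols$nha[3] <- 11
  sel <- select_references(mols, z, "DAT")
  expect_false(any(c("R01", "R02", "R03") %in% sel$id))
  expect_true(all(sel$avg_sc > 0.40))
  expect_true(all(sel$delta_g < -9.54))
  # survivors equal the independent three-filter scan
  expect_setequal(sel$id, brute_reference_ids(mols, z, "DAT"))
  # ranking: avg similarity desc, then more negative affinity, then id
  expect_true(all(diff(sel$avg_sc) <= 1e-12))
})

test_that("a Table-1-like record passes all selection criteria", {
  lip <- lipinski_filter(data.frame(mw = 300.140, logp = 4.464,
                                    nhd = 0, nha = 2))
  expect_true(lip$pass)
  expect_true(-14.18 < -9.54)
  expect_true(0.45 > 0.40)
})

test_that("selection survivors match a brute-force scan on a synthetic set", {
  spec <- synthetic_spec(n_per_target = 25L, targets = c("DAT", "NET"),
                         seed = 77)
  data <- make_latent_dataset(spec)
  for (t in c("DAT", "NET")) {
    sel <- select_references(data$molecules, data$latents, t)
    expect_setequal(sel$id, brute_reference_ids(data$molecules,
                                                data$latents, t))
    expect_true(all(sel$id %in% data$molecules$id))
  }
})
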