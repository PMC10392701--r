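test_that("quantile scoring matches the rank-based oracle", {
  scores <- function(x, q) as.integer(quantize_columns(cbind(x), q))
  ## brute-force oracle: score = number of strictly exceeded type-1
  ## empirical quartile boundaries
  oracle <- function(x, q) {
    br <- quantile(x, seq_len(q - 1) / q, type = 1, names = FALSE)
    vapply(x, function(xi) sum(xi > br), numeric(1))
  }
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  expect_equal(scores(x, 4), c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L))
  expect_equal(scores(x, 4), as.integer(oracle(x, 4)))
  set.seed(42)
  for (i in 1:20) {
    xi <- rnorm(50 + i)
    q <- sample(2:6, 1)
    expect_equal(scores(xi, q), as.integer(oracle(xi, q)))
  }
})

test_that("a column with exactly q distinct values gets the rank order", {
  x <- sample(c(10, 20, 30, 40))
  expect_equal(as.integer(quantize_columns(cbind(x), q = 4)), as.integer(rank(x) - 1))
})

test_that("scores are invariant to strictly monotone transforms", {
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(80)
    base <- quantize_columns(cbind(x), 4)
    for (f in list(exp, function(z) z^3, plogis, function(z) 5 * z - 2)) {
      expect_equal(quantize_columns(cbind(f(x)), 4), base,
                   ignore_attr = TRUE)
    }
  }
})

test_that("re-quantizing balanced scores returns them unchanged", {
  x <- rep(0:3, each = 10)[sample(40)]
  ## x has 4 distinct values in balanced classes
  expect_equal(as.integer(quantize_columns(cbind(x), 4)), x)
})

test_that("degenerate and missing inputs are rejected with the column named", {
  X <- cbind(good = rnorm(20), flat = rep(1, 20))
  expect_error(quantize_columns(X, 4), "flat")
  expect_error(quantize_columns(cbind(a = c(1, 2, NA, 4)), 2), "complete cases")
  expect_error(quantize_columns(cbind(a = c(1, 2, 3)), 4), "cannot form q groups")
})

test_that("mixture_data validates its invariants", {
  X <- matrix(rnorm(120), 30, 4, dimnames = list(NULL, letters[1:4]))
  d <- mixture_data(rnorm(30), X, q = 4)
  expect_s3_class(d, "mixture_data")
  expect_true(all(d$Q >= 0 & d$Q <= 3))
  expect_equal(dim(d), c(30L, 4L))
  expect_error(mixture_data(rnorm(30), X, q = 4, link = "logit"), "0/1")
  expect_error(mixture_data(rnorm(29), X), "same number of rows")
  Z <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, "a"))
  expect_error(mixture_data(rnorm(30), X, Z), "disjoint")
  ## binary outcome accepted under logit
  yb <- rbinom(30, 1, 0.5)
  db <- mixture_data(yb, X, q = 4, link = "logit")
  expect_equal(db$link, "logit")
})

test_that("CSV round trip preserves columns, supports prefixes and delimiters", {
  set.seed(3)
  df <- data.frame(out = rnorm(40), nutr_a = rnorm(40), nutr_b = rnorm(40),
                   age = rnorm(40))
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  d <- read_mixture_csv(f, outcome = "out", mixture = c("nutr_a", "nutr_b"),
                        covariates = "age")
  expect_equal(d$component_names, c("nutr_a", "nutr_b"))
  expect_equal(d$covariate_names, "age")
  d2 <- read_mixture_csv(f, outcome = "out", mixture = "nutr_*")
  expect_equal(d2$component_names, c("nutr_a", "nutr_b"))
  expect_error(read_mixture_csv(f, outcome = "out", mixture = "zzz"),
               "missing columns")
  ## semicolon-delimited
  f2 <- tempfile(fileext = ".csv")
  write.table(df, f2, sep = ";", row.names = FALSE)
  d3 <- read_mixture_csv(f2, outcome = "out", mixture = "nutr_*", delim = ";")
  expect_equal(d3$Q, d2$Q)
  ## writer emits the scores with original names
  fq <- tempfile(fileext = ".csv")
  write_quantized_csv(d, fq)
  back <- read.csv(fq)
  expect_equal(as.matrix(back), d$Q, ignore_attr = TRUE)
})
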