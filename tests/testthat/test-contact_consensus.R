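make_rr_file <- function(lines, header = "PFRMAT RR") {
  f <- withr::local_tempfile(fileext = ".rr", .local_envir = parent.frame())
  writeLines(c(header, lines, "END"), f)
  f
}

test_that("read_rr parses, normalizes and ranks contact records", {
  f <- make_rr_file(c("5 40 0 8 0.93", "40 4 0 8 0.95", "3 30 0 8 0.5",
                      "2 40 0 8 0.5"))
  po <- read_rr(f, L = 100, predictor_name = "respre")
  expect_s3_class(po, "PredictorOutput")
  expect_equal(po$category, "very_high")
  expect_equal(po$pairs$i[1:2], c(4, 5))       # 0.95 then 0.93
  expect_equal(po$pairs$j[1:2], c(40, 40))
  # ties at 0.5 broken by (i, j) ascending
  expect_equal(po$pairs[3:4, c("i", "j")],
               data.frame(i = c(2L, 3L), j = c(40L, 30L), row.names = 3:4))
})

test_that("read_rr rejects malformed and out-of-range records", {
  f <- make_rr_file("5 400 0 8 0.9")
  expect_error(read_rr(f, L = 100, category = "low"),
               class = "cf_index_range_error")
  f2 <- make_rr_file("5 x 0 8 0.9")
  expect_error(read_rr(f2, L = 100, category = "low"),
               class = "cf_malformed_rr_error")
  f3 <- make_rr_file("5 5 0 8 0.9")
  expect_error(read_rr(f3, L = 100, category = "low"),
               class = "cf_malformed_rr_error")
  expect_error(
    predictor_output("mystery", data.frame(i = 1, j = 30, confidence = 0.5)),
    class = "cf_unknown_predictor_error")
})

test_that("top_count applies the tier fractions with round-half-up", {
  expect_equal(top_count("medium", 90), 20)     # 90 / 4.5
  expect_equal(top_count("low", 90), 12)        # 90 / 7.5
  expect_equal(top_count("very_high", 1), 1)    # floor at 1
  expect_equal(top_count("very_high", 90), 90)
  expect_equal(top_count("high", 91), 46)       # 45.5 rounds half-up
})

test_that("build_consensus with one predictor is the truncated identity", {
  pairs <- data.frame(i = c(1, 2, 3), j = c(30, 40, 50),
                      confidence = c(0.9, 0.8, 0.7))
  po <- predictor_output("p", pairs, category = "very_high")
  cs <- build_consensus(list(po), L = 50, nf = 100)
  expect_equal(cs$contacts$u, pairs$confidence)
  expect_equal(cs$contacts$i, pairs$i)
})

test_that("build_consensus averages confidences over reporting predictors", {
  a <- predictor_output("a", data.frame(i = 5, j = 40, confidence = 0.8),
                        category = "very_high")
  b <- predictor_output("b", data.frame(i = 5, j = 40, confidence = 0.6),
                        category = "high")
  cs <- build_consensus(list(a, b), L = 50, nf = 100)
  expect_equal(cs$contacts$u, 0.7)
  expect_error(build_consensus(list(), L = 50), class = "cf_domain_error")
})

test_that("build_consensus equals an exhaustive set-union oracle", {
  set.seed(13)
  L <- 50
  make_po <- function(name, category, n) {
    seen <- c()
    rows <- list()
    while (length(rows) < n) {
      i <- sample(1:(L - 1), 1); j <- sample((i + 1):L, 1)
      key <- paste(i, j)
      if (key %in% seen) next
      seen <- c(seen, key)
      rows[[length(rows) + 1]] <- data.frame(i = i, j = j,
                                             confidence = runif(1, 0.1, 1))
    }
    predictor_output(name, do.call(rbind, rows), category = category)
  }
  pos <- list(make_po("a", "very_high", 60), make_po("b", "high", 40),
              make_po("c", "low", 20))
  cs <- build_consensus(pos, L = L, nf = 10)

  # oracle: truncate by hand, collect union, average per pair
  ks <- c(very_high = 50, high = 25, medium = 11, low = 7)
  bag <- list()
  for (po in pos) {
    k <- ks[[po$category]]
    top <- head(po$pairs, k)
    for (r in seq_len(nrow(top))) {
      key <- paste(top$i[r], top$j[r])
      bag[[key]] <- c(bag[[key]], top$confidence[r])
    }
  }
  expect_equal(nrow(cs$contacts), length(bag))
  for (r in seq_len(nrow(cs$contacts))) {
    key <- paste(cs$contacts$i[r], cs$contacts$j[r])
    expect_equal(cs$contacts$u[r], mean(bag[[key]]))
  }
})

test_that("consensus is invariant under predictor order", {
  set.seed(99)
  pairs <- function() data.frame(i = sample(1:20, 10), j = sample(30:49, 10),
                                 confidence = round(runif(10), 3))
  pos <- list(predictor_output("a", pairs(), category = "very_high"),
              predictor_output("b", pairs(), category = "medium"),
              predictor_output("c", pairs(), category = "low"))
  c1 <- build_consensus(pos, L = 50, nf = 10)
  c2 <- build_consensus(rev(pos), L = 50, nf = 10)
  expect_equal(c1$contacts, c2$contacts)
})

test_that("separation classes partition contacts at 12 and 24", {
  po <- predictor_output("p", data.frame(
    i = c(1, 1, 1, 1), j = c(2, 12, 25, 26),
    confidence = c(0.9, 0.8, 0.7, 0.6)), category = "very_high")
  cs <- build_consensus(list(po), L = 30, nf = 100)
  got <- cs$contacts$sep_class[order(cs$contacts$j)]
  expect_equal(got, c("short", "short", "medium", "long"))
})

test_that("long_range_subset keeps separation > 24 and truncates by weight", {
  po <- predictor_output("p", data.frame(
    i = c(1, 1, 1), j = c(11, 26, 31),
    confidence = c(0.9, 0.5, 0.8)), category = "very_high")
  cs <- build_consensus(list(po), L = 40, nf = 100)
  lr <- long_range_subset(cs, top = 10)
  expect_equal(sort(lr$contacts$j), c(26, 31))
  lr1 <- long_range_subset(cs, top = 1)
  expect_equal(lr1$contacts$j, 31)             # higher U wins
  expect_equal(nrow(long_range_subset(cs, top = 0)$contacts), 0)
})

test_that("RR round-trip preserves the consensus", {
  po <- predictor_output("p", data.frame(i = c(2, 3), j = c(30, 40),
                                         confidence = c(0.8, 0.6)),
                         category = "very_high")
  cs <- build_consensus(list(po), L = 40, nf = 100)
  f <- withr::local_tempfile(fileext = ".rr")
  write_rr(cs, f, target = "toy")
  back <- read_rr(f, L = 40, category = "very_high")
  expect_equal(back$pairs$i, cs$contacts$i)
  expect_equal(back$pairs$confidence, cs$contacts$u, tolerance = 1e-6)
})
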