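disc <- data.frame(cpg_id = c("d1", "d2", "d3"),
                   chromosome = c("1", "1", "2"),
                   position = c(100000, 200000, 300000),
                   stringsAsFactors = FALSE)

test_that("window and q-value rules decide validation", {
  val <- data.frame(
    site_id = c("v1", "v2", "v3"),
    chromosome = "1",
    position = c(100000 + 4999, 200000 + 5001, 100000),
    q_value = c(0.01, 0.01, 0.06), stringsAsFactors = FALSE)
  out <- vicinity_match(disc, val)
  expect_true(out$results$validated[out$results$cpg_id == "d1"])
  # +5,001 bp is outside the inclusive 5 kb window
  expect_false(out$results$validated[out$results$cpg_id == "d2"])
  # distance 0 but q = 0.06 fails the strict q < 0.05 rule (v3 vs d1 is
  # already covered by v1; check in isolation)
  solo <- vicinity_match(disc[1, ], val[3, , drop = FALSE])
  expect_false(solo$results$validated)
  # nearest match reported first
  expect_equal(out$matches$site_id[out$matches$cpg_id == "d1"], "v1")
  expect_equal(out$results$nearest_distance[1], 4999)
})

test_that("chromosome label conventions are normalized with a warning", {
  val <- data.frame(site_id = "v1", chromosome = "chr1", position = 100100,
                    q_value = 0.01, stringsAsFactors = FALSE)
  expect_warning(out <- vicinity_match(disc, val), "normalized")
  expect_true(out$results$validated[1])
})

test_that("validated count is monotone in window and q threshold", {
  withr::with_seed(21, {
    val <- data.frame(
      site_id = sprintf("v%03d", 1:200),
      chromosome = sample(c("1", "2"), 200, TRUE),
      position = sample(1e5:4e5, 200),
      q_value = runif(200), stringsAsFactors = FALSE)
    counts_w <- vapply(c(0, 1000, 5000, 20000, 100000), function(w) {
      sum(vicinity_match(disc, val, window = w)$results$validated)
    }, 0)
    expect_true(all(diff(counts_w) >= 0))
    counts_q <- vapply(c(0.001, 0.01, 0.05, 0.5, 1), function(q) {
      sum(vicinity_match(disc, val, q_threshold = q)$results$validated)
    }, 0)
    expect_true(all(diff(counts_q) >= 0))
  })
})

test_that("indexed matching agrees with brute force on random tables", {
  withr::with_seed(22, {
    for (rep in 1:5) {
      d <- data.frame(cpg_id = sprintf("d%02d", 1:10),
                      chromosome = sample(c("1", "2", "X"), 10, TRUE),
                      position = sample(1e4:1e6, 10),
                      stringsAsFactors = FALSE)
      v <- data.frame(site_id = sprintf("v%03d", 1:300),
                      chromosome = sample(c("1", "2", "X"), 300, TRUE),
                      position = sample(1e4:1e6, 300),
                      q_value = runif(300), stringsAsFactors = FALSE)
      got <- vicinity_match(d, v, window = 20000)$results$validated
      want <- vapply(seq_len(10), function(i) {
        any(v$chromosome == d$chromosome[i] &
              abs(v$position - d$position[i]) <= 20000 &
              v$q_value < 0.05)
      }, NA)
      expect_equal(got, want)
    }
  })
})

test_that("symmetric toy tables validate in both directions", {
  a <- data.frame(cpg_id = c("a1", "a2"), chromosome = "1",
                  position = c(1000, 50000), stringsAsFactors = FALSE)
  b <- data.frame(site_id = c("b1", "b2"), chromosome = "1",
                  position = c(2000, 51000), q_value = 0.01,
                  stringsAsFactors = FALSE)
  ab <- vicinity_match(a, b)
  b_as_disc <- data.frame(cpg_id = b$site_id, chromosome = b$chromosome,
                          position = b$position, stringsAsFactors = FALSE)
  a_as_val <- data.frame(site_id = a$cpg_id, chromosome = a$chromosome,
                         position = a$position, q_value = 0.01,
                         stringsAsFactors = FALSE)
  ba <- vicinity_match(b_as_disc, a_as_val)
  expect_equal(sum(ab$results$validated), sum(ba$results$validated))
})
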