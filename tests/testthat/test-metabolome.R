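test_that("normalization pairs post with pre samples per mouse", {
  mat <- matrix(c(100, 25, 80, 80), 1, dimnames = list("c1", NULL))
  colnames(mat) <- c("m1_pre", "m1_post", "m2_pre", "m2_post")
  pairing <- data.frame(post = c("m1_post", "m2_post"),
                        pre = c("m1_pre", "m2_pre"), mouse = 1:2)
  fc <- normalizeToReference(mat, pairing)
  expect_equal(unname(fc["c1", ]), c(0.25, 1))
  expect_error(normalizeToReference(mat, data.frame(post = "nope",
                                                    pre = "m1_pre",
                                                    mouse = 1)),
               "unpaired")
  # non-detects never fabricate ratios
  mat2 <- rbind(mat, c2 = c(NA, 50, 0, 50))
  fc2 <- normalizeToReference(mat2, pairing)
  expect_true(all(is.na(fc2["c2", ])))
})

test_that("BH adjustment agrees with the brute-force step-up everywhere", {
  expect_equal(bruteBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  set.seed(13)
  for (i in 1:1000) {
    p <- runif(sample(1:30, 1))
    expect_equal(stats::p.adjust(p, "BH"), bruteBH(p), tolerance = 1e-12)
  }
})

test_that("differential testing flags knocked-down compounds and not nulls", {
  set.seed(21)
  n_mice <- 5
  fc <- rbind(
    knocked = 0.1 * exp(rnorm(n_mice, 0, 0.2)),
    matrix(exp(rnorm(20 * n_mice, 0, 0.2)), 20,
           dimnames = list(paste0("null", 1:20), NULL)))
  dt <- differentialAbundance(fc, alpha = 0.05)
  expect_true(dt$significant[dt$compound == "knocked"])
  expect_equal(dt$direction[dt$compound == "knocked"], "down")
  expect_true(all(dt$p_adjusted >= dt$p_value, na.rm = TRUE))
  expect_identical(dt$significant, !is.na(dt$p_adjusted) & dt$p_adjusted < 0.05)
})

test_that("degenerate inputs are handled without fabricating significance", {
  fc <- rbind(flat = rep(1, 4),          # constant at no change: p = 1
              stuck = rep(2, 4),         # constant but nonzero: untestable
              short = c(1.2, NA, NA, NA))  # < 2 mice: untestable
  dt <- differentialAbundance(fc)
  expect_equal(dt$p_value[dt$compound == "flat"], 1)
  expect_false(dt$significant[dt$compound == "flat"])
  expect_true(dt$untestable[dt$compound == "stuck"])
  expect_true(is.na(dt$p_adjusted[dt$compound == "stuck"]))
  expect_true(dt$untestable[dt$compound == "short"])
})

test_that("identity pairing is a clean null at any alpha", {
  set.seed(31)
  mat <- matrix(rlnorm(40 * 5, 5, 1), 40,
                dimnames = list(paste0("c", 1:40), paste0("s", 1:5)))
  pairing <- data.frame(post = colnames(mat), pre = colnames(mat),
                        mouse = 1:5)
  dt <- differentialAbundance(normalizeToReference(mat, pairing),
                              alpha = 0.5)
  expect_equal(sum(dt$significant), 0L)
})

test_that("germfree presence needs detection in at least 4 of 5 mice", {
  mat <- rbind(four = c(1, 2, 3, 4, NA),
               three = c(1, 2, 3, NA, 0),
               five = c(1, 2, 3, 4, 5))
  pres <- presenceFilter(mat, min_detected = 4L)
  expect_identical(unname(pres), c(TRUE, FALSE, TRUE))
  expect_error(presenceFilter(mat, min_detected = 6L), "exceeds")
})

test_that("volcano summaries match a brute-force filter of the table", {
  set.seed(17)
  fc <- matrix(exp(rnorm(60 * 5, 0, 0.3)), 60,
               dimnames = list(paste0("c", 1:60), NULL))
  fc[1:6, ] <- fc[1:6, ] * 8     # strong increases
  fc[7:9, ] <- fc[7:9, ] / 16    # strong decreases
  dt <- differentialAbundance(fc, alpha = 0.05)
  vs <- volcanoSummary(dt)
  tested <- dt[!dt$untestable & !is.na(dt$p_value), ]
  expect_equal(vs$n_total, nrow(tested))
  expect_equal(vs$n_significant, sum(tested$p_adjusted < 0.05))
  expect_equal(vs$n_up, sum(tested$significant & tested$log2_fc > 0))
  expect_equal(vs$n_down, sum(tested$significant & tested$log2_fc < 0))
  expect_equal(vs$frac_up, vs$n_up / vs$n_total)
  # counting example: 10 compounds, 5 up, 2 down
  dt2 <- data.frame(compound = paste0("x", 1:10), p_value = 0.01,
                    p_adjusted = c(rep(0.01, 7), rep(0.9, 3)),
                    significant = c(rep(TRUE, 7), rep(FALSE, 3)),
                    direction = c(rep("up", 5), rep("down", 2),
                                  rep("none", 3)),
                    log2_fc = c(rep(1, 5), rep(-1, 2), rep(0, 3)),
                    untestable = FALSE)
  vs2 <- volcanoSummary(dt2)
  expect_equal(vs2$frac_up, 0.5)
  expect_equal(vs2$frac_down, 0.2)
})

test_that("cluster ordering is deterministic and matches naive agglomeration", {
  m <- rbind(a = c(0, 0, 0), b = c(0, 0, 0), c = c(5, 5, 5))
  co <- clusterOrder(m)
  expect_equal(co$row_hclust$height[1], 0)        # identical rows merge first
  expect_equal(sort(co$row_hclust$merge[1, ]), c(-2, -1))
  # 3 well-separated rows: nearest pair merges first, then the far row
  m3 <- rbind(p = c(0, 0), q = c(1, 0), r = c(10, 0))
  co3 <- clusterOrder(m3)
  expect_equal(sort(co3$row_hclust$merge[1, ]), c(-2, -1))  # p,q first (d=1)
  expect_equal(co3$row_hclust$height, c(1, 9.5))  # then average linkage to r
  # permuting rows permutes labels but not topology
  perm <- c(3, 1, 2)
  cop <- clusterOrder(m3[perm, ])
  expect_equal(sort(cop$row_hclust$height), sort(co3$row_hclust$height))
  part <- function(h, labels) {
    g <- stats::cutree(h, 2)
    unname(lapply(split(labels, g), sort)[order(vapply(
      split(labels, g), function(s) sort(s)[1], character(1)))])
  }
  expect_equal(part(co3$row_hclust, rownames(m3)),
               part(cop$row_hclust, rownames(m3[perm, ])))
  # single row is a trivial ordering; non-finite input is rejected
  expect_equal(clusterOrder(m3[1, , drop = FALSE])$row_order, 1L)
  m3[1, 1] <- NA
  expect_error(clusterOrder(m3), "finite")
})
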