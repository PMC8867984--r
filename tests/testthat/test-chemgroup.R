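test_that("bucketize maps features to the fixed RT x m/z grid", {
  g <- bucket_grid()  # 30-1080 s, 100-1600 m/z, 12 s, 5 ppm
  # grid origin
  b0 <- bucketize(data.frame(rt_s = 30, mz = 100, intensity = 5), g)
  expect_identical(names(b0$buckets), "0_0")
  expect_equal(b0$n_dropped, 0)

  # below the RT window: dropped and counted
  b1 <- bucketize(data.frame(rt_s = 29, mz = 500, intensity = 1), g)
  expect_length(b1$buckets, 0)
  expect_equal(b1$n_dropped, 1)

  # multiplicative m/z binning: floor(ln(5) / ln(1 + 5e-6)) = 321888
  b2 <- bucketize(data.frame(rt_s = 35, mz = 500, intensity = 2), g)
  expect_identical(names(b2$buckets), "0_321888")

  # intensities in the same bucket are summed, untransformed
  b3 <- bucketize(data.frame(rt_s = c(31, 32), mz = c(500, 500),
                             intensity = c(3, 4)), g)
  expect_equal(unname(b3$buckets), 7)
})

test_that("bucketize conserves total in-range intensity", {
  set.seed(3)
  g <- bucket_grid()
  f <- data.frame(rt_s = runif(200, 0, 1200),
                  mz = runif(200, 50, 1700),
                  intensity = rexp(200, 1 / 1000))
  b <- bucketize(f, g)
  in_range <- f$rt_s >= 30 & f$rt_s < 1080 & f$mz >= 100 & f$mz < 1600
  expect_equal(sum(b$buckets), sum(f$intensity[in_range]))
  expect_equal(b$n_dropped, sum(!in_range))
})

test_that("feature-count filter excludes samples strictly below the cut", {
  mk <- function(n) data.frame(rt_s = seq(31, 1000, length.out = n),
                               mz = runif(n, 100, 1500),
                               intensity = rep(1, n))
  fl <- list(a = mk(49), b = mk(50), c = mk(120))
  out <- feature_count_filter(fl, 50)
  expect_identical(names(out$retained), c("b", "c"))
  expect_identical(names(out$excluded), "a")
})

test_that("cosine similarity matches hand values and stays in range", {
  m <- rbind(x = c(1, 1, 0), y = c(1, 0, 0), z = c(0, 0, 2),
             w = c(2, 2, 0))
  S <- cosine_matrix(m)
  expect_equal(S["x", "y"], 1 / sqrt(2))
  expect_equal(round(S["x", "y"], 5), 0.70711)
  expect_equal(S["x", "w"], 1)        # identical direction
  expect_equal(S["y", "z"], 0)        # disjoint support
  expect_equal(diag(S), setNames(rep(1, 4), rownames(m)))
  expect_lt(max(abs(S - t(S))), 1e-12)
  expect_true(all(S >= 0 & S <= 1))

  expect_error(cosine_matrix(rbind(a = c(1, 0), b = c(0, 0))), "b")
})

test_that("clustering order puts the closest pair adjacent and is input-order invariant", {
  S <- diag(1, 3)
  rownames(S) <- colnames(S) <- c("a", "b", "c")
  S["a", "b"] <- S["b", "a"] <- 0.95
  S["a", "c"] <- S["c", "a"] <- 0.1
  S["b", "c"] <- S["c", "b"] <- 0.1
  ord <- order_samples(S)
  expect_equal(abs(diff(match(c("a", "b"), ord))), 1)

  # permuting the input leaves the leaf order unchanged
  p <- c("c", "a", "b")
  expect_identical(order_samples(S[p, p]), ord)

  # two samples: trivially the pair
  S2 <- matrix(c(1, .5, .5, 1), 2, dimnames = list(c("u", "v"), c("u", "v")))
  expect_identical(order_samples(S2), c("u", "v"))

  expect_error(order_samples(matrix(c(1, 0.2, 0.4, 1), 2)), "symmetric")
})

test_that("group assignment walks the order with the >= threshold rule", {
  g <- assign_groups(paste0("s", 1:4), c(0.95, 0.85, 0.92), 0.9)
  expect_equal(unname(g$groups), c(1, 1, 2, 2))
  expect_equal(max(g$groups), 2)

  # all adjacent pairs at/above the cut: one group (ties group together)
  g1 <- assign_groups(paste0("s", 1:3), c(0.9, 0.95), 0.9)
  expect_equal(unname(g1$groups), c(1, 1, 1))

  # all below: singletons
  gn <- assign_groups(paste0("s", 1:3), c(0.1, 0.2), 0.9)
  expect_equal(unname(gn$groups), 1:3)

  expect_error(assign_groups(paste0("s", 1:3), 0.5), "length")
})

test_that("group count is monotone non-increasing as the threshold drops", {
  set.seed(9)
  sims <- runif(19)
  counts <- vapply(seq(1, 0, by = -0.05), function(th)
    max(assign_groups(paste0("s", 1:20), sims, th)$groups), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("planted metabolic groups are recovered at the 0.9 rule", {
  syn <- gen_feature_tables(n_groups = 4, samples_per_group = 5,
                            seed = 101)
  mg <- metabolic_grouping(syn$feature_lists)
  expect_equal(max(mg$groups), 4)
  expect_true(partitions_equal(mg$groups, syn$true_groups))

  # permuting sample order must not change the grouping
  perm <- sample(names(syn$feature_lists))
  mg2 <- metabolic_grouping(syn$feature_lists[perm])
  expect_true(partitions_equal(mg2$groups, mg$groups))
})

test_that("long-format feature CSV reads into per-sample lists", {
  df <- data.frame(sample = rep(c("a", "b"), each = 2),
                   rt_s = c(31, 40, 31, 45), mz = c(150, 200, 150, 250),
                   intensity = c(1, 2, 3, 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  fl <- read_feature_lists(path)
  expect_identical(names(fl), c("a", "b"))
  expect_equal(nrow(fl$a), 2)
})
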