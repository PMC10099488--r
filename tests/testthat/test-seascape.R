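test_that("tidal fraction is the ratio of baseline-corrected amplitudes", {
  t <- seq(0, 48, by = 0.5)
  sea <- 2 + 0.25 * sin(t / 12.42 * 2 * pi)
  expect_equal(tidal_fraction(sea, sea), 1)
  lake <- 5 + 0.2 * sin(t / 12.42 * 2 * pi)
  expect_equal(tidal_fraction(lake, sea), 0.8, tolerance = 1e-9)
  expect_equal(tidal_fraction(rep(3, 10), sea), 0) # no exchange at all
  expect_error(tidal_fraction(lake, rep(1, 10)), "flat")
  expect_warning(tidal_fraction(sea * 2, sea), "clamping")
})

test_that("connection categories follow the survey thresholds", {
  expect_equal(categorize_connection(0.1), "low")
  expect_equal(categorize_connection(0.3), "low")
  expect_equal(categorize_connection(0.4), "low")
  expect_equal(categorize_connection(0.5), "medium")
  expect_equal(categorize_connection(0.7), "medium")
  expect_equal(categorize_connection(0.8), "high")
  expect_equal(categorize_connection(1.0), "high")
  expect_equal(categorize_connection("open"), "open")
  expect_message(expect_equal(categorize_connection(0.45), "medium"), "gap")
})

test_that("geographic distances are haversine on the 6371 km sphere", {
  prof <- data.frame(code = c("a", "b", "c"),
                     lat = c(0, 0, 0), lon = c(0, 1, 0))
  d <- geographic_distance_matrix(prof)
  expect_lt(abs(d["a", "b"] - 111195), 1) # 1 degree at the equator
  expect_equal(d["a", "c"], 0)
  expect_equal(unclass(d), t(unclass(d)))
  expect_true(all(diag(d) == 0))
})

test_that("environmental distance equals z-score distance (PCA rotation)", {
  prof <- data.frame(code = c("a", "b", "c"),
                     temperature_c = c(29, 31, 32.4),
                     salinity_ppt = c(33.5, 26, 24))
  d <- environment_distance_matrix(prof)
  z <- scale(as.matrix(prof[, 2:3]))
  expect_equal(unclass(d), as.matrix(dist(z)), tolerance = 1e-10,
               ignore_attr = TRUE)
  same <- data.frame(code = c("a", "b"), temperature_c = c(30, 30),
                     salinity_ppt = c(28, 28))
  expect_true(all(environment_distance_matrix(same) == 0))
  # similar environments sit closer than dissimilar ones
  expect_lt(d["b", "c"], d["a", "c"])
  prof$salinity_ppt[2] <- NA
  expect_error(environment_distance_matrix(prof), "missing")
})

test_that("connection distance is the mean isolation of the pair", {
  prof <- data.frame(code = c("s1", "s2", "iso", "con"),
                     tidal_fraction = c(NA, NA, 0.1, 0.8),
                     category = c("open", "open", "low", "high"))
  d <- connection_distance_matrix(prof)
  expect_equal(d["s1", "s2"], 0)       # two open-sea sites
  expect_equal(d["iso", "con"], 0.55)  # mixed pair strictly between
  expect_equal(d["iso", "iso"], 0)
  prof2 <- data.frame(code = c("a", "b"), tidal_fraction = c(0, 0),
                      category = c("low", "low"))
  expect_equal(connection_distance_matrix(prof2)["a", "b"], 1)
  # ordering contract: more connected partner always at most as distant
  for (ck in c(0, 0.35, 1)) {
    di <- ((1 - 0.2) + (1 - ck)) / 2
    dj <- ((1 - 0.7) + (1 - ck)) / 2
    expect_gte(di, dj)
  }
  prof3 <- rbind(prof, data.frame(code = "nofrac", tidal_fraction = NA,
                                  category = "medium"))
  expect_warning(connection_distance_matrix(prof3), "missing tidal fraction")
})

test_that("mantel reproduces trivial, exact, and cross-checked results", {
  set.seed(9)
  pts <- matrix(rnorm(20), 10)
  d1 <- as.matrix(dist(pts))
  mt <- mantel(d1, 2 * d1, n_perm = 199, seed = 1)
  expect_equal(mt$r, 1)
  expect_equal(mt$p, 1 / 200) # smallest attainable with the add-one rule
  # exact enumeration on 4x4 equals the brute-force oracle
  set.seed(10)
  a <- as.matrix(dist(rnorm(4)))
  b <- as.matrix(dist(rnorm(4)))
  mt_exact <- mantel(a, b, n_perm = "exact")
  oracle <- oracle_mantel_exact(a, b)
  expect_equal(mt_exact$r, oracle$r, tolerance = 1e-10)
  expect_equal(mt_exact$p, oracle$p, tolerance = 1e-10)
  # vegan agrees on the statistic (independent implementation)
  skip_if_not_installed("vegan")
  d2 <- as.matrix(dist(matrix(rnorm(20), 10)))
  vg <- vegan::mantel(d1, d2, permutations = 499)
  expect_equal(mantel(d1, d2, n_perm = 499, seed = 2)$r,
               unname(vg$statistic), tolerance = 1e-10)
  # relabeling both matrices identically leaves the test invariant
  perm <- sample(10)
  mt1 <- mantel(d1, d2, n_perm = 299, seed = 3)
  mt2 <- mantel(d1[perm, perm], d2[perm, perm], n_perm = 299, seed = 3)
  expect_equal(mt1$r, mt2$r, tolerance = 1e-12)
  expect_lt(abs(mt1$p - mt2$p), 0.1)
  # constant matrix flagged
  flat <- matrix(0, 5, 5)
  expect_true(is.na(mantel(flat, flat, n_perm = 9)$r))
})

test_that("F'ST linearisation is x/(1-x) with a cap at 1", {
  m <- matrix(c(0, 0.5, 0.63, 0.5, 0, 0, 0.63, 0, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  lin <- linearize_fst(m)
  expect_equal(lin["a", "b"], 1.0)
  expect_equal(lin["a", "c"], 1.7027, tolerance = 1e-4)
  expect_equal(lin["b", "c"], 0)
  m[1, 2] <- m[2, 1] <- 1
  expect_warning(lin2 <- linearize_fst(m), "capped")
  expect_true(is.finite(lin2["a", "b"]))
})

test_that("spearman correlations flag strength and significance", {
  prof <- data.frame(code = sprintf("L%d", 1:8),
                     area_1000m2 = c(4, 6, 13, 14, 22, 89, 140, 232),
                     tidal_fraction = c(0.1, 0.1, 0.3, 0.4, 0.5, 0.5, 0.8, 0.8),
                     salinity_ppt = c(24, 25.9, 26, 27, 28.9, 28.9, 30.7, 31),
                     temperature_c = c(29.5, 29.5, 29.5, 30, 31.2, 31.5, 31.7, 32.3))
  div <- data.frame(population = prof$code,
                    pi = c(1, 2, 3, 4, 5, 6, 7, 8) / 1000,
                    he = c(8, 7, 6, 5, 4, 3, 2, 1) / 100)
  res <- spearman_diversity(div, prof, predictors = "area_1000m2")
  expect_equal(res$rho[res$response == "pi"], 1)
  expect_equal(res$rho[res$response == "he"], -1)
  expect_true(all(res$strong))
  # tie-corrected rho equals the direct rank-formula oracle
  res2 <- spearman_diversity(div, prof, predictors = "tidal_fraction",
                             responses = "pi")
  r_oracle <- {
    rx <- rank(prof$tidal_fraction); ry <- rank(div$pi)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  expect_equal(res2$rho, r_oracle, tolerance = 1e-12)
  expect_warning(
    spearman_diversity(div[1:4, ], prof[1:4, ], predictors = "area_1000m2",
                       responses = "pi"),
    "paired observations")
})

test_that("profile summaries reproduce the survey table statistics", {
  prof <- read_lake_profiles()
  sm <- summarize_profiles(prof)
  expect_equal(unname(sm$lake_means["mean", "temperature_c"]), 30.8,
               tolerance = 0.05)
  expect_equal(unname(sm$lake_means["sd", "temperature_c"]), 1.2,
               tolerance = 0.05)
  expect_equal(unname(sm$lake_means["mean", "salinity_ppt"]), 27.3,
               tolerance = 0.05)
  expect_equal(unname(sm$lake_means["sd", "salinity_ppt"]), 2.7,
               tolerance = 0.05)
  expect_equal(unname(sm$category_counts["low"]), 4)
  expect_equal(unname(sm$category_counts["high"]), 2)
  expect_equal(sm$n_individuals, 125)
  expect_equal(unname(sm$n_by_lineage["B"]), 105)
})

test_that("distance matrices can be checked against each other (no
           autocorrelation guard)", {
  prof <- read_lake_profiles()
  prof_c <- prof[!is.na(prof$temperature_c), ]
  set.seed(30)
  prof_c$lat <- runif(nrow(prof_c), -9, 2)
  prof_c$lon <- runif(nrow(prof_c), 112, 134)
  geo <- geographic_distance_matrix(prof_c)
  env <- environment_distance_matrix(prof_c)
  mt <- mantel(geo, env, n_perm = 499, seed = 4)
  expect_true(is.finite(mt$r))
  expect_true(mt$p > 0 && mt$p <= 1)
})
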