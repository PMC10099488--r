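# Seascape module: lake profiling (tidal-connection metric and categories),
# the four distance matrices (genomic linearised F'ST, geographic,
# environmental, connection-resistance), Mantel tests, and Spearman
# correlations of diversity against lake predictors.

#' Read a lake-profile table
#'
#' Expects the tab-separated layout shipped in
#' `system.file("extdata", "lake_profiles.tsv", package = "lakerad")`: the
#' eleven Indo-Pacific sampling sites (nine marine lakes, two open lagoons)
#' with connection category, tidal-amplitude fraction, area, depth, mean
#' temperature and salinity, individuals passing QC, mitochondrial lineage,
#' and the per-site diversity estimates.
#'
#' @param path Path to a TSV; default is the packaged survey table.
#' @return data.frame of lake profiles.
#' @export
read_lake_profiles <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "lake_profiles.tsv", package = "lakerad")
  }
  read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
}

#' Tidal-amplitude fraction of a lake
#'
#' `c = max(lake amplitude) / max(sea amplitude)` from simultaneous
#' water-level series, each baseline-corrected by subtracting its minimum.
#' c = 1 means unobstructed exchange; c = 0 means no exchange at all.
#'
#' @param lake_series,sea_series Water levels over the same >= 48 h window.
#' @return c in `[0, 1]` (values > 1 clamped with a warning).
#' @export
tidal_fraction <- function(lake_series, sea_series) {
  stopifnot(length(lake_series) > 1, length(sea_series) > 1)
  amp_lake <- max(lake_series) - min(lake_series)
  amp_sea <- max(sea_series) - min(sea_series)
  if (amp_sea == 0) stop("sea series is flat: tidal fraction undefined")
  c_val <- amp_lake / amp_sea
  if (c_val > 1) {
    warning("lake amplitude exceeds sea amplitude; clamping c to 1")
    c_val <- 1
  }
  c_val
}

#' Connection category from the tidal fraction
#'
#' Thresholds: low (c <= 0.4), medium (0.5-0.7), high (0.8-1); open-sea
#' sites pass through as "open". Values in the scheme's gap (0.4, 0.5) are
#' assigned "medium" with a message.
#'
#' @param c_frac Tidal fraction in `[0, 1]`, or the string "open".
#' @return One of "low", "medium", "high", "open".
#' @export
categorize_connection <- function(c_frac) {
  if (identical(c_frac, "open")) return("open")
  stopifnot(is.numeric(c_frac), c_frac >= 0, c_frac <= 1)
  if (c_frac <= 0.4) return("low")
  if (c_frac < 0.5) {
    message("c = ", c_frac, " falls in the (0.4, 0.5) gap of the category ",
            "scheme; assigning 'medium'")
    return("medium")
  }
  if (c_frac < 0.8) return("medium")
  "high"
}

new_distance_matrix <- function(m, labels, kind) {
  dimnames(m) <- list(labels, labels)
  stopifnot(isTRUE(all.equal(m, t(m))), all(diag(m) == 0), all(m >= 0, na.rm = TRUE))
  structure(m, kind = kind, class = c("distance_matrix", "matrix", "array"))
}

#' Great-circle distance matrix between lakes (meters)
#'
#' Haversine distances (Earth radius 6,371,000 m) from the profile
#' coordinates.
#'
#' @param profiles data.frame with `code`, `lat`, `lon`.
#' @return Symmetric `distance_matrix` in meters.
#' @export
geographic_distance_matrix <- function(profiles) {
  stopifnot(all(c("lat", "lon") %in% names(profiles)))
  xy <- as.matrix(profiles[, c("lon", "lat")])
  m <- geosphere::distm(xy, fun = function(a, b) {
    geosphere::distHaversine(a, b, r = 6371000)
  })
  new_distance_matrix(m, profiles$code, "geographic_m")
}

#' Environmental distance matrix
#'
#' Standardises the environmental variables (default mean temperature and
#' salinity), rotates them by PCA, and takes Euclidean distances on all
#' retained axes — which, retaining all axes, equals the z-score Euclidean
#' distance. Low values mean similar lake environments.
#'
#' @param profiles Profile data.frame.
#' @param variables Column names to use (no missing values allowed).
#' @return Symmetric `distance_matrix`.
#' @export
environment_distance_matrix <- function(profiles,
                                        variables = c("temperature_c",
                                                      "salinity_ppt")) {
  stopifnot(length(variables) >= 2)
  X <- profiles[, variables, drop = FALSE]
  if (anyNA(X)) {
    stop("missing environmental values for: ",
         paste(profiles$code[!stats::complete.cases(X)], collapse = ", "))
  }
  X <- as.matrix(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  Z <- sweep(sweep(X, 2, mu), 2, ifelse(sdv > 0, sdv, 1), `/`)
  scores <- prcomp(Z, center = FALSE, scale. = FALSE)$x
  m <- as.matrix(dist(scores))
  new_distance_matrix(m, profiles$code, "environment")
}

#' Connection (resistance) distance matrix
#'
#' `d(i, j) = ((1 - c_i) + (1 - c_j)) / 2`: the mean isolation of the pair.
#' Two open-sea sites (c = 1) are at distance 0; two fully isolated lakes
#' (c = 0) at distance 1; mixed pairs fall strictly in between, so the
#' matrix behaves as a resistance surface. Open sites take c = 1; lakes
#' with missing c are excluded with a warning.
#'
#' @param profiles Profile data.frame with `tidal_fraction` and `category`.
#' @return Symmetric `distance_matrix` (possibly on a subset of sites).
#' @export
connection_distance_matrix <- function(profiles) {
  c_val <- profiles$tidal_fraction
  c_val[profiles$category == "open"] <- 1
  drop <- is.na(c_val)
  if (any(drop)) {
    warning("excluding site(s) with missing tidal fraction: ",
            paste(profiles$code[drop], collapse = ", "))
  }
  c_val <- c_val[!drop]
  iso <- 1 - c_val
  m <- outer(iso, iso, `+`) / 2
  diag(m) <- 0
  new_distance_matrix(m, profiles$code[!drop], "connection_resistance")
}

#' Linearise pairwise F'ST
#'
#' Elementwise `x / (1 - x)`, the standard linearisation for
#' distance-matrix comparisons. Entries at or above 1 are mapped to `cap`
#' with a warning.
#'
#' @param fst Symmetric F'ST matrix (or `pairwise_differentiation`).
#' @param cap Replacement for F'ST = 1 before linearising.
#' @return Symmetric `distance_matrix`.
#' @export
linearize_fst <- function(fst, cap = 0.999) {
  if (inherits(fst, "pairwise_differentiation")) fst <- fst$fst
  x <- as.matrix(fst)
  if (any(x >= 1, na.rm = TRUE)) {
    warning("F'ST value(s) at 1 capped at ", cap, " before linearising")
    x[x >= 1] <- cap
  }
  m <- x / (1 - x)
  diag(m) <- 0
  new_distance_matrix(m, rownames(x), "genomic_linearized")
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

#' Mantel test between two distance matrices
#'
#' `r` is the Pearson correlation of the upper-triangle entries; the
#' one-sided p-value permutes rows and columns of `d2` simultaneously,
#' using the add-one estimator `p = (1 + #{r_perm >= r_obs}) / (1 +
#' n_perm)`. With `n_perm = "exact"` all `n!` label permutations are
#' enumerated and p is the exact proportion with `r_perm >= r_obs`
#' (identity included).
#'
#' @param d1,d2 Distance matrices with matching labels.
#' @param n_perm Number of permutations (study default 10,000), or
#'   `"exact"` (n <= 8).
#' @param seed Integer seed.
#' @return List of class `mantel_result`: `r`, `p`, `n_perm`, `seed`.
#' @export
mantel <- function(d1, d2, n_perm = 10000, seed = 1) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  stopifnot(nrow(d1) == nrow(d2))
  if (!is.null(rownames(d1)) && !is.null(rownames(d2))) {
    stopifnot(identical(rownames(d1), rownames(d2)))
  }
  ut <- upper.tri(d1)
  x <- d1[ut]
  if (sd(x) == 0 || sd(d2[ut]) == 0) {
    return(structure(list(r = NA_real_, p = NA_real_, n_perm = n_perm,
                          seed = seed, flag = "constant matrix: r undefined"),
                     class = "mantel_result"))
  }
  r_obs <- cor(x, d2[ut])
  n <- nrow(d1)
  if (identical(n_perm, "exact")) {
    if (n > 8) stop("exact enumeration limited to n <= 8")
    perms <- all_permutations(n)
    rs <- apply(perms, 1, function(p) cor(x, d2[p, p][ut]))
    p_val <- mean(rs >= r_obs - 1e-12)
  } else {
    exceed <- with_seed(seed, {
      sum(replicate(n_perm, {
        p <- sample.int(n)
        cor(x, d2[p, p][ut]) >= r_obs - 1e-12
      }))
    })
    p_val <- (1 + exceed) / (1 + n_perm)
  }
  structure(list(r = r_obs, p = p_val, n_perm = n_perm, seed = seed),
            class = "mantel_result")
}

#' Spearman correlations of diversity with lake predictors
#'
#' Tie-corrected Spearman rho between each diversity index and each
#' predictor, two-sided p; correlations are flagged "strong" at
#' `|rho| >= 0.5` and "significant" at `p < 0.01` (the study's thresholds).
#' Fewer than 5 paired observations triggers a warning but the test still
#' runs.
#'
#' @param diversity_table data.frame with `population` plus response
#'   columns.
#' @param profiles Profile data.frame with `code` and predictor columns.
#' @param predictors Predictor column names.
#' @param responses Response column names.
#' @return data.frame response, predictor, rho, p, n, strong, significant.
#' @export
spearman_diversity <- function(diversity_table, profiles,
                               predictors = c("area_1000m2", "tidal_fraction",
                                              "salinity_ppt", "temperature_c"),
                               responses = c("pi", "he")) {
  merged <- merge(diversity_table, profiles,
                  by.x = "population", by.y = "code",
                  suffixes = c("", ".profile"))
  out <- list()
  for (resp in responses) for (pred in predictors) {
    x <- merged[[pred]]; y <- merged[[resp]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 5) {
      warning("only ", sum(ok), " paired observations for ", resp, " ~ ", pred)
    }
    if (sum(ok) < 3) next
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman"))
    out[[paste(resp, pred)]] <- data.frame(
      response = resp, predictor = pred, rho = unname(ct$estimate),
      p = ct$p.value, n = sum(ok),
      strong = abs(ct$estimate) >= 0.5, significant = ct$p.value < 0.01,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarise lake profiles against the open-lagoon reference
#'
#' Arithmetic mean and sample SD (n-1 denominator) of temperature and
#' salinity over the lake rows (category != "open"), the lagoon values for
#' comparison, connection-category counts, and individual totals per
#' lineage.
#'
#' @param profiles Profile data.frame (see [read_lake_profiles()]).
#' @return List: `lake_means` (mean/sd per variable), `lagoon_values`,
#'   `category_counts`, `n_individuals`, `n_by_lineage`.
#' @export
summarize_profiles <- function(profiles) {
  is_lake <- profiles$category != "open"
  if (!any(is_lake) || all(is_lake)) {
    stop("need at least one lake and one open lagoon row")
  }
  vars <- c("temperature_c", "salinity_ppt")
  lake_means <- sapply(vars, function(v) {
    x <- profiles[[v]][is_lake]
    c(mean = mean(x, na.rm = TRUE), sd = sd(x, na.rm = TRUE))
  })
  lagoon <- profiles[!is_lake, c("code", vars)]
  counts <- table(factor(profiles$category[is_lake],
                         levels = c("low", "medium", "high")))
  out <- list(lake_means = lake_means, lagoon_values = lagoon,
              category_counts = counts)
  if ("n_passed_qc" %in% names(profiles)) {
    out$n_individuals <- sum(profiles$n_passed_qc, na.rm = TRUE)
  }
  if ("lineage" %in% names(profiles)) {
    out$n_by_lineage <- tapply(profiles$n_passed_qc, profiles$lineage, sum)
  }
  out
}
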