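test_that("age binning uses left-closed bins with an inclusive last bin", {
  expect_equal(as.character(bin_age(39.9)), "<40")
  expect_equal(as.character(bin_age(40)), "40-60")
  expect_equal(as.character(bin_age(60)), "60-80")
  expect_equal(as.character(bin_age(85)), ">=80")
  expect_equal(as.character(bin_age(c(18, 90))), c("<40", ">=80"))
  expect_error(bin_age(17), "range")
  expect_error(bin_age(91), "range")
})

test_that("vocabulary ranks by distinct-encounter frequency with lexicographic ties", {
  dx <- data.frame(encounter_id = c(1, 1, 1, 2, 2, 3, 3),
                   icd_code = c("Z9", "Z9", "A1", "A1", "B2", "B2", "C3"))
  md <- data.frame(encounter_id = c(1, 2, 3),
                   med_name = c("m1", "m1", "m2"))
  w <- testthat::capture_warnings(v <- build_vocabulary(dx, md, top_n = 500))
  expect_match(w, "distinct", all = TRUE)
  # duplicate within encounter 1 counted once: Z9 has 1 encounter, A1/B2 two
  expect_equal(v$top_diagnoses[1:2], c("A1", "B2"))  # tie at 2 -> lexicographic
  expect_equal(v$dx_counts[1:2], c(2L, 2L))
  expect_equal(length(v$top_diagnoses), 4L)
  # cap enforcement with a tie at the cut
  suppressWarnings({
    v2 <- build_vocabulary(dx, md, top_n = 3)
  })
  expect_equal(v2$top_diagnoses, c("A1", "B2", "C3"))  # C3 beats Z9 (tie, lex)
  expect_error(suppressWarnings(build_vocabulary(dx[0, ], md)), "empty")
})

test_that("one-hot encoding has the partition and zero-block properties", {
  ev <- data.frame(encounter_id = 1:3, age_years = c(35, 62, 81),
                   sex = c("Female", "Male", "Female"),
                   race = c("Caucasian", "Black", "Other race"),
                   ethnicity = c("Hispanic", "Non-Hispanic", "Non-Hispanic"),
                   icu = c(TRUE, FALSE, FALSE),
                   telemetry = c(TRUE, TRUE, FALSE),
                   stepdown = c(FALSE, TRUE, FALSE),
                   obgyn = FALSE)
  dx <- data.frame(encounter_id = c(1, 2), icd_code = c("A1", "B2"))
  md <- data.frame(encounter_id = c(1), med_name = c("m1"))
  suppressWarnings(v <- build_vocabulary(dx, md))
  X <- encode_features(ev, v, dx, md)
  expect_true(all(X %in% 0:1))
  age_block <- X[, 1:4]
  expect_equal(rowSums(age_block), rep(1, 3))       # exactly one age bin
  # encounter 3 has no vocabulary codes: all-zero code block
  code_cols <- grep("^(dx|med):", colnames(X))
  expect_equal(sum(X[3, code_cols]), 0)
  expect_equal(X[1, "dx:A1"], c(`dx:A1` = 1L))
  expect_equal(X[1, "med:m1"], c(`med:m1` = 1L))
})

test_that("Hamming K-means solves the canonical 4-point example", {
  X <- rbind(c(0, 0, 0), c(0, 0, 1), c(1, 1, 0), c(1, 1, 1))
  m <- kmeans_hamming(X, 2, seed = 1, n_init = 10)
  expect_equal(m$inertia, 2)
  expect_equal(m$labels[1], m$labels[2])
  expect_equal(m$labels[3], m$labels[4])
  expect_false(m$labels[1] == m$labels[3])
  # k = number of distinct rows -> zero inertia
  expect_equal(kmeans_hamming(X, 4, seed = 1)$inertia, 0)
  # duplication invariance: duplicated rows, same centroids, doubled inertia
  m2 <- kmeans_hamming(rbind(X, X), 2, seed = 1, n_init = 10)
  expect_equal(m2$inertia, 2 * m$inertia)
  expect_setequal(apply(m2$centroids, 1, paste, collapse = ""),
                  apply(m$centroids, 1, paste, collapse = ""))
})

test_that("Hamming K-means attains the exhaustive optimum on tiny instances", {
  set.seed(7)
  for (trial in 1:4) {
    n <- sample(5:7, 1); p <- sample(4:6, 1); k <- sample(2:3, 1)
    X <- matrix(rbinom(n * p, 1, 0.5), n, p)
    opt <- brute_force_kmodes(X, k)
    got <- kmeans_hamming(X, k, seed = trial, n_init = 25)$inertia
    expect_equal(got, opt, info = sprintf("trial %d (n=%d,p=%d,k=%d)",
                                          trial, n, p, k))
  }
})

test_that("majority-bit centroids are inertia-minimizing for fixed labels", {
  set.seed(8)
  X <- matrix(rbinom(60, 1, 0.4), 12, 5)
  m <- kmeans_hamming(X, 3, seed = 2, n_init = 5)
  inertia_for <- function(C) {
    D <- rowSums(abs(X - C[m$labels, , drop = FALSE]))
    sum(D)
  }
  base <- inertia_for(m$centroids)
  expect_equal(base, m$inertia)
  for (j in seq_len(nrow(m$centroids)))
    for (c in seq_len(ncol(m$centroids))) {
      C2 <- m$centroids
      C2[j, c] <- 1 - C2[j, c]
      expect_gte(inertia_for(C2), base)
    }
})

test_that("inertia trace is non-increasing within a fit", {
  pl <- plant_archetypes(300, 25, k = 4, flip_rate = 0.15, seed = 3)
  m <- kmeans_hamming(pl$X, 4, seed = 5, n_init = 1)
  expect_true(all(diff(m$inertia_trace) <= 0))
})

test_that("planted archetypes are recovered and the elbow sits at k = 4", {
  pl <- plant_archetypes(2000, 40, k = 4, flip_rate = 0.05, seed = 42)
  m <- kmeans_hamming(pl$X, 4, seed = 1, n_init = 5)
  expect_gte(adjusted_rand_index(m$labels, pl$labels), 0.9)
  curve <- elbow_scan(pl$X, k_range = 2:8, seed = 9, sample_n = 1500)
  expect_equal(select_k_elbow(curve), 4L)
  # refinement: more clusters never help less
  expect_gte(curve$inertia[1], curve$inertia[nrow(curve)])
})

test_that("constant-row matrices give zero inertia for any k", {
  X <- matrix(1, 20, 6)
  expect_equal(kmeans_hamming(X, 2, seed = 1)$inertia, 0)
  expect_equal(kmeans_hamming(X, 5, seed = 1)$inertia, 0)
})

test_that("assignment is deterministic with lowest-index tie-break", {
  pl <- plant_archetypes(100, 20, k = 3, flip_rate = 0.05, seed = 6)
  m <- kmeans_hamming(pl$X, 3, seed = 2, n_init = 5)
  # centroid rows map to their own cluster
  expect_equal(assign_clusters(m$centroids, m), 1:3)
  # refitting assignment reproduces fitted labels
  expect_equal(assign_clusters(pl$X, m), m$labels)
  # an equidistant row goes to the lowest cluster index
  C <- rbind(c(0, 0, 0, 0), c(1, 1, 1, 1))
  model <- structure(list(k = 2L, centroids = C), class = "qtcds_cluster_model")
  expect_equal(assign_clusters(matrix(c(1, 1, 0, 0), 1), model), 1L)
  expect_error(assign_clusters(matrix(0, 1, 3), model), "columns")
})

test_that("cluster models round-trip through the text artifact", {
  pl <- plant_archetypes(80, 12, k = 2, flip_rate = 0.1, seed = 10)
  m <- kmeans_hamming(pl$X, 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_cluster_model(m, path)
  m2 <- read_cluster_model(path)
  expect_equal(unname(m2$centroids), unname(m$centroids))
  expect_equal(m2$inertia, m$inertia)
  expect_equal(assign_clusters(pl$X, m2), m$labels)
})

test_that("pipeline clustering separates generated archetypes", {
  fx <- medium_events()
  ev <- fx$ev
  b <- fx$ds$bundle
  v <- suppressWarnings(build_vocabulary(b$diagnoses, b$medications_list))
  X <- encode_features(ev, v, b$diagnoses, b$medications_list)
  m <- kmeans_hamming(X, 4, seed = 7, n_init = 3)
  arch <- fx$ds$ground_truth$patient_archetype[ev$patient_id]
  # code blocks carry archetype signal: far better than chance agreement
  expect_gte(adjusted_rand_index(m$labels, arch), 0.3)
  # PCA sanity: top-2 principal components separate the centroids
  pc <- stats::prcomp(X, rank. = 2)
  proj <- predict(pc, m$centroids)
  expect_gt(min(dist(proj)), 0)
})
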