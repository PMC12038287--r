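# Comorbidity clustering: one-hot feature construction over the top-500
# diagnosis and medication codes plus demographics, and K-means with
# Hamming distance (binary-mode centroids), with elbow-based selection of
# the cluster count.

#' Bin age into the four analysis categories
#'
#' Bins are left-closed/right-open — \[18,40), \[40,60), \[60,80) — except
#' the last, \[80,90\]: the printed bin labels overlap at their boundaries
#' and need a convention, so a 40th birthday falls in the 40-60 bin.
#'
#' @param age_years numeric age(s) in \[18, 90\].
#' @return factor with levels `<40`, `40-60`, `60-80`, `>=80`.
#' @export
bin_age <- function(age_years) {
  if (any(age_years < 18 | age_years > 90, na.rm = TRUE))
    stop("age out of the analysis range [18, 90]", call. = FALSE)
  cut(age_years, breaks = c(18, 40, 60, 80, 90),
      labels = c("<40", "40-60", "60-80", ">=80"),
      right = FALSE, include.lowest = TRUE)
}

#' Build the clustering feature vocabulary
#'
#' The top (up to) 500 diagnosis codes and top 500 medication names, ranked
#' by the number of distinct encounters each appears in; rank ties are
#' broken lexicographically. A code occurring twice in one encounter counts
#' once.
#'
#' @param diagnoses table with `encounter_id`, `icd_code`.
#' @param medications_list table with `encounter_id`, `med_name`.
#' @param top_n cap per code family (default 500).
#' @return list of class `qtcds_vocabulary` with `top_diagnoses`,
#'   `top_medications` (character, frequency-ranked) and the counts.
#' @export
build_vocabulary <- function(diagnoses, medications_list, top_n = 500) {
  rank_tokens <- function(tab, col, label) {
    d <- data.table::as.data.table(tab)
    if (nrow(d) == 0) stop(label, " table is empty", call. = FALSE)
    cnt <- unique(d[, c("encounter_id", col), with = FALSE])
    cnt <- cnt[, .N, by = c(col)]
    data.table::setnames(cnt, col, "token")
    data.table::setorder(cnt, -N, token)
    if (nrow(cnt) < top_n)
      warning("only ", nrow(cnt), " distinct ", label,
              " tokens (< ", top_n, "): using all", call. = FALSE)
    utils::head(cnt, top_n)
  }
  dx <- rank_tokens(diagnoses, "icd_code", "diagnosis")
  md <- rank_tokens(medications_list, "med_name", "medication")
  structure(list(top_diagnoses = dx$token, top_medications = md$token,
                 dx_counts = dx$N, med_counts = md$N),
            class = "qtcds_vocabulary")
}

#' One-hot encode index events against a vocabulary
#'
#' Row per event (encounter-medication entry): demographics one-hot (four
#' age bins, female sex, three race levels, Hispanic ethnicity, four
#' location flags) followed by the diagnosis and medication code blocks
#' (present yes/no within the encounter).
#'
#' @param events index events with `encounter_id`, `age_years`, `sex`,
#'   `race`, `ethnicity`, `icu`, `telemetry`, `stepdown`, `obgyn`.
#' @param vocab a [build_vocabulary()] result.
#' @param diagnoses,medications_list the code tables.
#' @return binary integer matrix; rownames are event row indices.
#' @export
encode_features <- function(events, vocab, diagnoses, medications_list) {
  stopifnot(inherits(vocab, "qtcds_vocabulary"))
  ev <- data.table::as.data.table(events)
  n <- nrow(ev)
  ab <- bin_age(ev$age_years)
  demo <- cbind(
    `age<40` = ab == "<40", `age40-60` = ab == "40-60",
    `age60-80` = ab == "60-80", `age>=80` = ab == ">=80",
    sex_female = ev$sex == "Female",
    race_caucasian = ev$race == "Caucasian",
    race_black = ev$race == "Black",
    race_other = !ev$race %in% c("Caucasian", "Black"),
    hispanic = ev$ethnicity == "Hispanic",
    icu = as.logical(ev$icu), telemetry = as.logical(ev$telemetry),
    stepdown = as.logical(ev$stepdown), obgyn = as.logical(ev$obgyn))
  block <- function(tab, col, tokens, prefix) {
    d <- unique(data.table::as.data.table(tab)[, c("encounter_id", col),
                                               with = FALSE])
    data.table::setnames(d, col, "token")
    d <- d[token %in% tokens]
    m <- matrix(0L, n, length(tokens),
                dimnames = list(NULL, paste0(prefix, tokens)))
    if (nrow(d)) {
      ri <- match(d$encounter_id, ev$encounter_id)
      # one encounter can back several events; map token hits to all of them
      hits <- d[, .(token)]
      idx <- data.table::data.table(enc = d$encounter_id, tok = d$token)
      evmap <- data.table::data.table(enc = ev$encounter_id, row = seq_len(n))
      j <- merge(idx, evmap, by = "enc", allow.cartesian = TRUE)
      m[cbind(j$row, match(j$tok, tokens))] <- 1L
    }
    m
  }
  X <- cbind(demo * 1L,
             block(diagnoses, "icd_code", vocab$top_diagnoses, "dx:"),
             block(medications_list, "med_name", vocab$top_medications, "med:"))
  storage.mode(X) <- "integer"
  X
}

# n x k Hamming distance between binary rows of X and centroid rows of C.
hamming_distances <- function(X, C) {
  rs <- rowSums(X)
  cs <- rowSums(C)
  outer(rs, rep(1, nrow(C))) + outer(rep(1, length(rs)), cs) -
    2 * (X %*% t(C))
}

#' K-means clustering with Hamming distance on binary vectors
#'
#' Lloyd-style alternation for binary data: rows are assigned to the
#' nearest centroid in Hamming distance (ties to the lowest cluster index)
#' and each centroid is recomputed as the per-column majority bit, with
#' exact 50% ties resolved to 0 (deterministic, and favors sparsity of the
#' code features). The majority bit minimizes total Hamming distance for a
#' fixed assignment, so inertia is non-increasing across iterations. An
#' emptied cluster is reseeded with the row farthest from its current
#' centroid. Initial centroids are `k` distinct rows sampled under the
#' seed; `n_init` restarts (seeds `seed`, `seed+1`, ...) keep the best
#' final inertia.
#'
#' @param X binary matrix (rows = encounters/events).
#' @param k number of clusters (>= 2, <= distinct rows).
#' @param seed integer seed for initialization.
#' @param max_iter iteration cap (default 100).
#' @param n_init number of random restarts (default 5).
#' @return object of class `qtcds_cluster_model`: `k`, `centroids` (binary
#'   k x p matrix), `labels`, `inertia`, `inertia_trace`, `n_iter`, `seed`.
#' @export
kmeans_hamming <- function(X, k, seed = 1L, max_iter = 100L, n_init = 5L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (nrow(X) < k) stop("fewer rows than clusters", call. = FALSE)
  best <- NULL
  for (init in seq_len(n_init)) {
    fit <- kmeans_hamming_once(X, k, seed + init - 1L, max_iter)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  best$seed <- as.integer(seed)
  class(best) <- "qtcds_cluster_model"
  best
}

kmeans_hamming_once <- function(X, k, seed, max_iter) {
  set.seed(seed)
  # k-means++-style seeding on distinct rows: the first centroid is a
  # uniformly sampled row, later ones are rows sampled with probability
  # proportional to the squared Hamming distance from the nearest chosen
  # centroid (plain random rows collapse badly on sparse one-hot data)
  ux <- unique(X)
  if (nrow(ux) < k) {
    C <- X[sample.int(nrow(X), k), , drop = FALSE]
  } else {
    C <- ux[sample.int(nrow(ux), 1), , drop = FALSE]
    for (j in 2:k) {
      d2 <- apply(hamming_distances(ux, C), 1, min)^2
      if (sum(d2) == 0) d2 <- rep(1, nrow(ux))
      C <- rbind(C, ux[sample.int(nrow(ux), 1, prob = d2), ])
    }
  }
  labels <- rep(0L, nrow(X))
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    D <- hamming_distances(X, C)
    new_labels <- max.col(-D, ties.method = "first")
    mind <- D[cbind(seq_len(nrow(X)), new_labels)]
    # reseed empty clusters with the row farthest from its centroid
    for (j in which(tabulate(new_labels, k) == 0L)) {
      far <- which.max(mind)
      C[j, ] <- X[far, ]
      new_labels[far] <- j
      mind[far] <- 0
    }
    trace <- c(trace, sum(mind))
    if (identical(new_labels, labels)) break
    labels <- new_labels
    for (j in seq_len(k)) {
      nj <- sum(labels == j)
      C[j, ] <- as.numeric(colSums(X[labels == j, , drop = FALSE]) > nj / 2)
    }
  }
  D <- hamming_distances(X, C)
  labels <- max.col(-D, ties.method = "first")
  list(k = as.integer(k), centroids = C, labels = labels,
       inertia = sum(D[cbind(seq_len(nrow(X)), labels)]),
       inertia_trace = trace, n_iter = iter)
}

#' Assign rows to the nearest centroid of a fitted cluster model
#'
#' @param X binary matrix with the model's column layout.
#' @param model a `qtcds_cluster_model`.
#' @return integer cluster labels (ties to the lowest cluster index).
#' @export
assign_clusters <- function(X, model) {
  stopifnot(inherits(model, "qtcds_cluster_model"))
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$centroids))
    stop("feature matrix has ", ncol(X), " columns; model expects ",
         ncol(model$centroids), call. = FALSE)
  D <- hamming_distances(X, model$centroids)
  max.col(-D, ties.method = "first")
}

#' Inertia curve over a range of cluster counts (elbow scan)
#'
#' Fits [kmeans_hamming()] for each `k` on a without-replacement sample of
#' rows (all rows if the sample exceeds the population) and reports the
#' final inertia, for elbow-based selection of the cluster count.
#'
#' @param X binary matrix.
#' @param k_range integer vector of cluster counts (default `2:30`).
#' @param seed seed controlling both the sample and the fits.
#' @param sample_n sample size (default 10000).
#' @param n_init restarts per k (default 3).
#' @return data.table with columns `k`, `inertia`.
#' @export
elbow_scan <- function(X, k_range = 2:30, seed = 1L, sample_n = 10000L,
                       n_init = 3L) {
  X <- as.matrix(X)
  set.seed(seed)
  rows <- if (nrow(X) > sample_n) sample.int(nrow(X), sample_n)
          else seq_len(nrow(X))
  Xs <- X[rows, , drop = FALSE]
  inertia <- vapply(k_range, function(k)
    kmeans_hamming(Xs, k, seed = seed + k, n_init = n_init)$inertia,
    numeric(1))
  data.table::data.table(k = as.integer(k_range), inertia = inertia)
}

#' Pick the elbow of an inertia curve by maximum second difference
#'
#' @param curve result of [elbow_scan()].
#' @return the selected k (interior maximizer of
#'   `inertia[k-1] - 2 inertia[k] + inertia[k+1]`).
#' @export
select_k_elbow <- function(curve) {
  stopifnot(nrow(curve) >= 3)
  d2 <- diff(diff(curve$inertia))      # aligned with interior ks
  curve$k[which.max(d2) + 1L]
}

#' Generate a planted-archetype binary matrix (test utility)
#'
#' Draws `k` random binary archetype centroids and emits rows as archetype
#' copies with independent bit flips, for recovery tests of the Hamming
#' K-means.
#'
#' @param n rows; @param p columns; @param k archetypes;
#' @param flip_rate per-bit flip probability; @param seed seed.
#' @return list with `X`, `labels`, `centroids`.
#' @export
plant_archetypes <- function(n, p, k = 4, flip_rate = 0.05, seed = 1L) {
  set.seed(seed)
  centroids <- matrix(stats::rbinom(k * p, 1, 0.5), k, p)
  labels <- sample.int(k, n, replace = TRUE)
  flips <- matrix(stats::rbinom(n * p, 1, flip_rate), n, p)
  X <- abs(centroids[labels, , drop = FALSE] - flips)
  list(X = X, labels = labels, centroids = centroids)
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b integer/factor label vectors of equal length.
#' @return the adjusted Rand index (1 = identical partitions, ~0 = chance).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Serialize a cluster model as structured text
#'
#' Centroids are stored as 0/1 strings so the artifact is diff-friendly.
#'
#' @param model a `qtcds_cluster_model`; @param path output file.
#' @return `path`, invisibly.
#' @export
write_cluster_model <- function(model, path) {
  stopifnot(inherits(model, "qtcds_cluster_model"))
  obj <- list(k = model$k, seed = model$seed, inertia = model$inertia,
              n_iter = model$n_iter,
              columns = colnames(model$centroids),
              centroids = apply(model$centroids, 1, paste, collapse = ""))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a cluster model written by [write_cluster_model()]
#' @param path file path.
#' @return a `qtcds_cluster_model` (without labels or trace).
#' @export
read_cluster_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  C <- do.call(rbind, lapply(strsplit(obj$centroids, ""), as.numeric))
  colnames(C) <- obj$columns
  structure(list(k = obj$k, centroids = C, labels = NULL,
                 inertia = obj$inertia, n_iter = obj$n_iter,
                 seed = obj$seed),
            class = "qtcds_cluster_model")
}
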