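# Inter-channel connectivity (groups E and F): Pearson correlation and
# phase-locking value matrices, summarized by a fixed list of 20 graph
# measures.

#' Inter-channel Pearson correlation matrix (group E input)
#'
#' @param seg An [eeg_recording()] / `eeg_segment`.
#' @return A `connectivity_matrix`: symmetric channels x channels matrix with
#'   unit diagonal and attribute `kind = "correlation"`.
#' @export
correlation_matrix <- function(seg) {
  check_recording(seg)
  sds <- apply(seg$data, 1, sd)
  if (any(sds == 0)) {
    abort(paste0("zero-variance channel(s): ",
                 paste(seg$channel_names[sds == 0], collapse = ", ")))
  }
  m <- cor(t(seg$data))
  new_connectivity(m, "correlation", seg$channel_names)
}

#' Inter-channel phase-locking value matrix (group F input)
#'
#' PLV between channels X and Y is `|mean(exp(i (phi_X - phi_Y)))|` over
#' time, with instantaneous phases taken from the analytic signal (FFT-based
#' Hilbert transform) of each (already band-passed) channel. 1 means perfect
#' phase locking, 0 none.
#'
#' @inheritParams correlation_matrix
#' @return A `connectivity_matrix` with entries in `[0, 1]`, unit diagonal
#'   and attribute `kind = "plv"`.
#' @export
plv_matrix <- function(seg) {
  check_recording(seg)
  phases <- t(apply(seg$data, 1, function(x) Arg(analytic_signal(x))))
  nch <- n_channels(seg)
  m <- diag(1, nch)
  for (i in seq_len(nch - 1)) {
    for (j in (i + 1):nch) {
      v <- Mod(mean(exp(1i * (phases[i, ] - phases[j, ]))))
      m[i, j] <- v; m[j, i] <- v
    }
  }
  new_connectivity(m, "plv", seg$channel_names)
}

new_connectivity <- function(m, kind, channel_names) {
  dimnames(m) <- list(channel_names, channel_names)
  structure(m, kind = kind, class = c("connectivity_matrix", "matrix", "array"))
}

#' Analytic signal via the FFT Hilbert transform
#'
#' @param x Real numeric vector.
#' @return Complex vector whose real part is `x` and whose argument is the
#'   instantaneous phase.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Twenty graph-theoretical summaries of a connectivity matrix (groups E/F)
#'
#' The weighted graph on `|edge weight|` is summarized by a fixed list of 20
#' measures. Ten are global: edge density after proportional thresholding at
#' 0.5 (the strongest half of the 210 pairs is kept), binary transitivity,
#' average local clustering, global efficiency and characteristic path length
#' (distance `1/weight`), greedy modularity, degree assortativity, and the
#' mean, maximum and standard deviation of node strength. Ten aggregate
#' per-channel centralities: mean and maximum of degree, betweenness,
#' closeness, eigenvector centrality and local efficiency. Assortativity is
#' undefined on degree-regular graphs and is reported as 0 there so every
#' output is finite.
#'
#' @param mat A `connectivity_matrix` (or any symmetric matrix with unit
#'   diagonal).
#' @param threshold Proportion of strongest edges retained for the binary
#'   (thresholded) measures.
#' @return Named numeric vector of length 20.
#' @export
graph_features <- function(mat, threshold = 0.5) {
  if (!isSymmetric(unclass(mat), tol = 1e-8)) {
    abort("connectivity matrix must be symmetric.")
  }
  w <- abs(unclass(mat))
  diag(w) <- 0
  nch <- nrow(w)
  # proportional threshold: keep the strongest `threshold` fraction of pairs
  ut <- w[upper.tri(w)]
  cut <- quantile(ut, probs = 1 - threshold, type = 1)
  bin <- (w >= cut) * 1                   # >= keeps tied weights (complete graph stays complete)
  diag(bin) <- 0
  g_w <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
  g_b <- igraph::graph_from_adjacency_matrix(bin, mode = "undirected",
                                             diag = FALSE)
  dist_w <- 1 / igraph::E(g_w)$weight
  strength <- igraph::strength(g_w)
  finite0 <- function(v) ifelse(is.finite(v), v, 0)
  glob <- c(
    density = mean(bin[upper.tri(bin)]),
    transitivity = finite0(igraph::transitivity(g_b, type = "global")),
    avg_clustering = finite0(mean(igraph::transitivity(
      g_b, type = "local", isolates = "zero"))),
    global_efficiency = igraph::global_efficiency(g_w, weights = dist_w),
    char_path_length = igraph::mean_distance(g_w, weights = dist_w),
    modularity = igraph::modularity(igraph::cluster_fast_greedy(g_w)),
    assortativity = finite0(igraph::assortativity_degree(g_b)),
    strength_mean = mean(strength),
    strength_max = max(strength),
    strength_sd = sd(strength)
  )
  betw <- igraph::betweenness(g_w, weights = dist_w, normalized = TRUE)
  clos <- finite0(igraph::closeness(g_w, weights = dist_w, normalized = TRUE))
  eig <- igraph::eigen_centrality(g_w)$vector
  loce <- finite0(igraph::local_efficiency(g_w, weights = dist_w))
  deg <- igraph::degree(g_b)
  nodal <- c(
    degree_mean = mean(deg), degree_max = max(deg),
    betweenness_mean = mean(betw), betweenness_max = max(betw),
    closeness_mean = mean(clos), closeness_max = max(clos),
    eigenvector_mean = mean(eig), eigenvector_max = max(eig),
    local_efficiency_mean = mean(loce), local_efficiency_max = max(loce)
  )
  c(glob, nodal)
}
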