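# Independent oracles used across the suite. Each re-implements the checked
# quantity by a different route than the package (explicit operator
# matrices, brute-force scans, direct enumeration).

# --- reflected-padding Gaussian convolution, as an explicit 257x257
# operator matrix (whole-sample reflection, period 512). The 2-D smooth is
# A %*% W %*% t(A).
oracle_reflect_operator <- function(kernel_sd) {
  sigma_g <- kernel_sd * 256
  k <- 0:511
  kern <- exp(-0.5 * (pmin(k, 512 - k) / sigma_g)^2)
  kern <- kern / sum(kern)
  A <- matrix(0, 257, 257)
  for (i in 0:256) {
    for (o in -256:255) {
      m <- (i + o) %% 512
      src <- if (m > 256) 512 - m else m
      A[i + 1, src + 1] <- A[i + 1, src + 1] + kern[(o %% 512) + 1]
    }
  }
  A
}

oracle_smooth <- function(weights, kernel_sd) {
  A <- oracle_reflect_operator(kernel_sd)
  S <- A %*% weights %*% t(A)
  S[S < 0] <- 0
  S
}

oracle_trapz <- function(arr) {
  wt <- rep(1, 257); wt[c(1, 257)] <- 0.5
  as.numeric(t(wt) %*% arr %*% wt) / 256^2
}

# --- brute-force sliding-window noise floor
oracle_noise_floor <- function(density, weights, kernel_sd, sigma_noise = 3) {
  L <- max(1, round((4 * kernel_sd * 256)^2))
  ix <- (seq_along(density) - 1) %% 257
  iy <- (seq_along(density) - 1) %/% 257
  ord <- order(density, ix * 257 + iy)
  d <- density[ord]; w <- weights[ord]
  if (L >= length(d)) return(if (sum(w) > sigma_noise^2) max(d) else Inf)
  for (s in seq_len(length(d) - L + 1)) {
    if (sum(w[s:(s + L - 1)]) > sigma_noise^2) return(d[s + L - 1])
  }
  Inf
}

# --- greedy steepest-ascent watershed labels (4-neighbour), above threshold
oracle_watershed <- function(density, threshold) {
  N <- 257
  lab <- matrix(0L, N, N)
  ord <- order(-density, ((seq_along(density) - 1) %% N) * N +
                 (seq_along(density) - 1) %/% N)
  next_mode <- 0L
  for (idx in ord) {
    if (density[idx] < threshold) break
    ix <- (idx - 1) %% N + 1; iy <- (idx - 1) %/% N + 1
    best <- 0; best_lab <- 0L
    for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      x <- ix + sh[1]; y <- iy + sh[2]
      if (x < 1 || x > N || y < 1 || y > N) next
      if (lab[x, y] > 0 && density[x, y] > best) {
        best <- density[x, y]; best_lab <- lab[x, y]
      }
    }
    if (best_lab == 0L) { next_mode <- next_mode + 1L; lab[ix, iy] <- next_mode }
    else lab[ix, iy] <- best_lab
  }
  lab
}

# --- brute-force candidate separations: every face 2-partition with both
# sides adjacency-connected and a continuous cut curve
oracle_candidates <- function(graph) {
  faces <- graph$faces$face
  F <- length(faces)
  edge_faces <- lapply(graph$edges, `[[`, "faces")
  eps <- lapply(graph$edges, `[[`, "endpoints")
  masks <- character(0)
  sides_connected <- function(S) {
    if (length(S) <= 1) return(length(S) == 1)
    sel <- vapply(edge_faces, function(f) all(f %in% S), TRUE)
    if (!any(sel)) return(FALSE)
    df <- do.call(rbind, edge_faces[sel])
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(df[, 1]), to = as.character(df[, 2])),
      directed = FALSE, vertices = data.frame(name = as.character(S)))
    igraph::components(g)$no == 1
  }
  curve_continuous <- function(ids) {
    ep <- eps[ids]
    if (any(lengths(ep) == 0)) return(length(ids) == 1)
    keys <- unlist(ep)
    # multigraph: one node per key occurrence set; degree by table
    tab <- table(keys)
    if (any(tab > 2)) return(FALSE)
    odd <- names(tab)[tab == 1]
    if (!(length(odd) %in% c(0, 2))) return(FALSE)
    if (length(odd) && !all(grepl("^B", odd))) return(FALSE)
    if (length(ids) == 1) return(TRUE)
    inc <- igraph::graph_from_data_frame(
      data.frame(from = rep(paste0("E", seq_along(ids)), lengths(ep)), to = keys),
      directed = FALSE)
    igraph::components(inc)$no == 1
  }
  for (code in 0:(2^(F - 1) - 2)) {
    inS <- c(TRUE, as.logical(bitwAnd(code, 2^(seq_len(F - 1) - 1))))
    S <- faces[inS]; Sb <- faces[!inS]
    if (!sides_connected(S) || !sides_connected(Sb)) next
    cut <- which(vapply(edge_faces, function(f)
      xor(f[1] %in% S, f[2] %in% S), TRUE))
    if (length(cut) == 0) next
    if (!curve_continuous(cut)) next
    masks <- c(masks, sprintf("%.0f", sum(2^(cut - 1))))
  }
  sort(masks)
}

# --- minimal FCS 3.1 writer (float32, little-endian), for reader tests
write_test_fcs <- function(path, mat, names = colnames(mat)) {
  npar <- ncol(mat); ntot <- nrow(mat)
  kv <- c("$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
          "$PAR", npar, "$TOT", ntot, "$NEXTDATA", "0")
  for (i in seq_len(npar))
    kv <- c(kv, paste0("$P", i, "N"), names[i],
            paste0("$P", i, "B"), "32",
            paste0("$P", i, "E"), "0,0",
            paste0("$P", i, "R"), "262144")
  text <- paste0("/", paste(kv, collapse = "/"), "/")
  text_beg <- 64
  text_end <- text_beg + nchar(text) - 1
  data_beg <- text_end + 1
  data_end <- data_beg + 4 * npar * ntot - 1
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_beg, text_end, data_beg, data_end, 0, 0)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(raw(text_beg - nchar(header)), con)
  writeBin(charToRaw(text), con)
  writeBin(as.numeric(t(mat)), con, size = 4, endian = "little")
  invisible(path)
}

# standard two- and five-component study fixtures
fixture_two_comp <- function(n = 20000, seed = 1, sd = 0.04)
  generate_mixture(tibble::tibble(weight = c(.5, .5),
                                  mean = list(c(.3, .5), c(.7, .5)), sd = sd),
                   n_events = n, seed = seed)

fixture_five_comp <- function(n = 50000, seed = 1)
  generate_mixture(tibble::tibble(
    weight = rep(.2, 5),
    mean = list(c(.2, .2), c(.8, .2), c(.5, .5), c(.2, .8), c(.8, .8)),
    sd = 0.04), n_events = n, seed = seed)

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
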