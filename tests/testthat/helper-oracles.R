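# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain-R recursion/DP for alignment scores,
# sliding-window Hamming scans for motifs, exhaustive six-frame enumeration
# for ORFs, and least-squares fits over enumerated topologies for trees.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")
random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

# Exhaustive enumeration of every gapped global alignment (no memoisation):
# returns the optimal affine-gap score. A gap run of length L costs
# open + L * ext. Only usable for tiny sequences.
oracle_enum_align <- function(a, b, sub = blosum62, open = 10, ext = 0.5) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  rec <- function(i, j, last) {
    if (i > length(A) && j > length(B)) return(0)
    best <- -Inf
    if (i <= length(A) && j <= length(B))
      best <- max(best, sub[A[i], B[j]] + rec(i + 1L, j + 1L, "m"))
    if (i <= length(A))
      best <- max(best, -(if (last == "d") ext else open + ext) +
                    rec(i + 1L, j, "d"))
    if (j <= length(B))
      best <- max(best, -(if (last == "i") ext else open + ext) +
                    rec(i, j + 1L, "i"))
    best
  }
  rec(1L, 1L, "m")
}

# Independent affine-gap DP (Gotoh three-state recurrence) in plain R.
oracle_gotoh <- function(a, b, sub = blosum62, open = 10, ext = 0.5) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e18
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)  # gap in b (consumes a)
  Y <- matrix(NEG, n + 1L, m + 1L)  # gap in a (consumes b)
  M[1L, 1L] <- 0
  for (i in seq_len(n + 1L)) {
    for (j in seq_len(m + 1L)) {
      if (i > 1L && j > 1L)
        M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                       Y[i - 1L, j - 1L]) + sub[A[i - 1L], B[j - 1L]]
      if (i > 1L)
        X[i, j] <- max(M[i - 1L, j] - open - ext, X[i - 1L, j] - ext,
                       Y[i - 1L, j] - open - ext)
      if (j > 1L)
        Y[i, j] <- max(M[i, j - 1L] - open - ext, X[i, j - 1L] - open - ext,
                       Y[i, j - 1L] - ext)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

# Sliding-window Hamming motif scan.
oracle_motif_scan <- function(seq, defs) {
  s <- strsplit(seq, "")[[1]]
  rows <- list()
  for (k in seq_len(nrow(defs))) {
    p <- strsplit(defs$pattern[k], "")[[1]]
    w <- length(p)
    if (w > length(s)) next
    for (i in seq_len(length(s) - w + 1L)) {
      nm <- sum(s[i:(i + w - 1L)] != p)
      if (nm <= defs$max_mismatch[k]) {
        rows[[length(rows) + 1L]] <- data.frame(
          motif = defs$name[k], pattern = defs$pattern[k], start = i,
          end = i + w - 1L,
          observed = paste(s[i:(i + w - 1L)], collapse = ""),
          n_mismatch = nm, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif = character(), pattern = character(), start = integer(),
               end = integer(), observed = character(),
               n_mismatch = integer(), stringsAsFactors = FALSE)
  out <- out[order(out$start, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exhaustive six-frame start-to-stop ORF enumeration using the standard
# genetic code; returns the translation of the longest ORF >= min_aa (frame
# order +1,+2,+3,-1,-2,-3 breaks ties, earliest start within frame), or NULL.
oracle_longest_orf <- function(nt, min_aa) {
  code <- Biostrings::GENETIC_CODE
  revcomp <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
  }
  translate_frame <- function(x, off) {
    s <- strsplit(x, "")[[1]]
    s <- s[(off + 1L):length(s)]
    ncod <- length(s) %/% 3L
    if (ncod == 0L) return(character())
    vapply(seq_len(ncod), function(k)
      unname(code[paste(s[(3L * k - 2L):(3L * k)], collapse = "")]),
      character(1))
  }
  best <- NULL
  for (frame in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    x <- if (frame > 0L) nt else revcomp(nt)
    aa <- translate_frame(x, abs(frame) - 1L)
    if (!length(aa)) next
    for (s in which(aa == "M")) {
      stops <- which(aa == "*")
      stops <- stops[stops > s]
      if (!length(stops)) next
      e <- stops[1L] - 1L
      len <- e - s + 1L
      if (len >= min_aa && (is.null(best) || len > best$len))
        best <- list(protein = paste(aa[s:e], collapse = ""), len = len,
                     frame = frame)
    }
  }
  best
}

# Connected components of the thresholded identity graph, by brute force
# over all label pairs (transitive closure).
oracle_components <- function(m, cut) {
  n <- nrow(m)
  adj <- m >= cut
  diag(adj) <- TRUE
  reach <- adj
  for (k in seq_len(n))
    reach <- reach | (reach %*% (reach * 1) > 0)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      comp[which(reach[i, ])] <- cur
    }
  }
  comp
}

# Least-squares branch lengths for a fixed topology against a distance
# matrix; returns the residual sum of squares and fitted edge lengths.
ls_fit_tree <- function(topology, d) {
  labels <- rownames(d)
  n <- length(labels)
  pairs <- t(combn(n, 2))
  nedge <- nrow(topology$edge)
  # indicator matrix: which edges lie on the path between each leaf pair,
  # read off by setting one edge to length 1 at a time
  A <- matrix(0, nrow(pairs), nedge)
  for (p in seq_len(nrow(pairs))) {
    tr <- topology
    tr$edge.length <- rep(0, nedge)
    for (e in seq_len(nedge)) {
      tr$edge.length[] <- 0
      tr$edge.length[e] <- 1
      dm <- ape::cophenetic.phylo(tr)
      A[p, e] <- dm[labels[pairs[p, 1]], labels[pairs[p, 2]]]
    }
  }
  y <- d[cbind(labels[pairs[, 1]], labels[pairs[, 2]])]
  fit <- stats::lm.fit(A, y)
  rss <- sum(fit$residuals^2)
  list(rss = rss, lengths = fit$coefficients)
}

# build an additive distance matrix from a random unrooted tree with
# positive branch lengths, scaled so distances stay below 100
random_additive <- function(n, min_len = 0.5, max_len = 6) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), min_len, max_len)
  d <- ape::cophenetic.phylo(tr)
  list(tree = tr, d = d, identity = {
    m <- 100 - d
    diag(m) <- 100
    m
  })
}
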