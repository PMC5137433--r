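# Independent brute-force oracles. These deliberately share no code with
# the package internals: plain loops and arithmetic on coordinate vectors.

# element-wise >= 1 bp overlap between two interval sets (1-based closed)
brute_overlaps_any <- function(a_start, a_end, b_start, b_end) {
  vapply(seq_along(a_start), function(i)
    any(a_start[i] <= b_end & b_start <= a_end[i]), NA)
}

gr_fields <- function(gr) {
  list(chrom = as.character(GenomicRanges::seqnames(gr)),
       start = GenomicRanges::start(gr), end = GenomicRanges::end(gr))
}

# per-chromosome brute overlap for GRanges
brute_gr_overlaps_any <- function(a, b) {
  fa <- gr_fields(a); fb <- gr_fields(b)
  vapply(seq_along(fa$start), function(i) {
    sel <- fb$chrom == fa$chrom[i]
    any(fa$start[i] <= fb$end[sel] & fb$start[sel] <= fa$end[i])
  }, NA)
}

# all pairwise base intersections of a and b, merged (1-based closed)
brute_intersect_merge <- function(a, b) {
  fa <- gr_fields(a); fb <- gr_fields(b)
  pieces <- list()
  for (i in seq_along(fa$start)) {
    for (j in seq_along(fb$start)) {
      if (fa$chrom[i] != fb$chrom[j]) next
      s <- max(fa$start[i], fb$start[j])
      e <- min(fa$end[i], fb$end[j])
      if (s <= e) pieces[[length(pieces) + 1L]] <- c(s, e, i = i)
    }
  }
  if (!length(pieces))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  df <- data.frame(
    chrom = vapply(seq_along(pieces), function(k) {
      fa$chrom[pieces[[k]]["i"]]
    }, ""),
    start = vapply(pieces, `[`, 0, 1L),
    end = vapply(pieces, `[`, 0, 2L))
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  # merge overlapping or book-ended pieces
  out <- df[0, ]
  for (k in seq_len(nrow(df))) {
    n <- nrow(out)
    if (n && out$chrom[n] == df$chrom[k] && df$start[k] <= out$end[n] + 1L) {
      out$end[n] <- max(out$end[n], df$end[k])
    } else out <- rbind(out, df[k, ])
  }
  rownames(out) <- NULL
  out
}

# linear-scan island finder: explicit position walk, no vectorised grouping
island_scan_oracle <- function(counts, lambda, l0, gap = 0L) {
  islands <- list()
  cur <- NULL
  last_elig <- -Inf
  for (i in seq_along(counts)) {
    if (counts[i] >= l0) {
      if (!is.null(cur) && (i - last_elig - 1L) <= gap) {
        cur$last <- i
        cur$members <- c(cur$members, i)
      } else {
        if (!is.null(cur)) islands[[length(islands) + 1L]] <- cur
        cur <- list(first = i, last = i, members = i)
      }
      last_elig <- i
    }
  }
  if (!is.null(cur)) islands[[length(islands) + 1L]] <- cur
  do.call(rbind, lapply(islands, function(x)
    data.frame(first = x$first, last = x$last,
               score = sum(-dpois(counts[x$members], lambda, log = TRUE)),
               tag_count = sum(counts[x$members]))))
}

# Poisson tail scan for the eligibility threshold
eligibility_oracle <- function(lambda, p) {
  for (l0 in 0:1000) {
    tail_prob <- 1 - sum(dpois(0:(l0 - 1L), lambda))
    if (l0 == 0L) tail_prob <- 1
    if (tail_prob < p) return(l0)
  }
  stop("no threshold found")
}

# character-walk G4 scanner (1-based inclusive coordinates)
g4_oracle <- function(s, base = "G", min_run = 3L, n_runs = 4L,
                      loop_min = 1L, loop_max = 7L) {
  chars <- strsplit(toupper(s), "")[[1L]]
  n <- length(chars)
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (chars[i] == base) {
      j <- i
      while (j < n && chars[j + 1L] == base) j <- j + 1L
      if (j - i + 1L >= min_run) runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  motifs <- list()
  k <- 1L
  while (k <= length(runs)) {
    m <- k
    while (m < length(runs)) {
      gap <- runs[[m + 1L]][1L] - runs[[m]][2L] - 1L
      gap_chars <- if (gap > 0L)
        chars[(runs[[m]][2L] + 1L):(runs[[m + 1L]][1L] - 1L)] else character()
      if (gap >= loop_min && gap <= loop_max && !any(gap_chars == "N"))
        m <- m + 1L
      else break
    }
    if (m - k + 1L >= n_runs)
      motifs[[length(motifs) + 1L]] <- c(runs[[k]][1L], runs[[m]][2L])
    k <- m + 1L
  }
  if (!length(motifs))
    return(data.frame(start = integer(), end = integer()))
  data.frame(start = vapply(motifs, `[`, 0L, 1L),
             end = vapply(motifs, `[`, 0L, 2L))
}

# direct base-count skew of one window
skew_oracle <- function(w) {
  ch <- strsplit(toupper(w), "")[[1L]]
  term <- function(x, y) {
    nx <- sum(ch == x); ny <- sum(ch == y)
    if (nx + ny == 0) 0 else (nx - ny) / (nx + ny)
  }
  term("T", "A") + term("G", "C")
}

random_dna <- function(n, gc = 0.41, with_n = FALSE) {
  letters <- c("A", "C", "G", "T")
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  if (with_n) {
    letters <- c(letters, "N")
    prob <- c(prob * 0.98, 0.02)
  }
  paste(sample(letters, n, replace = TRUE, prob = prob), collapse = "")
}

random_granges <- function(n, chroms = c("chrA", "chrB"), L = 100000L,
                           max_width = 2000L) {
  chr <- sample(chroms, n, replace = TRUE)
  start <- sample.int(L - max_width, n, replace = TRUE)
  width <- sample.int(max_width, n, replace = TRUE)
  GenomicRanges::GRanges(factor(chr, levels = chroms),
                         IRanges::IRanges(start, start + width - 1L))
}
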