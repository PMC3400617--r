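# Independent brute-force oracles, deliberately written as naive loops with
# their own constants so they share no code path with the package.

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", U = "A")
  ch <- strsplit(x, "")[[1]]
  out <- character(length(ch))
  for (i in seq_along(ch)) out[length(ch) - i + 1] <- comp[[ch[i]]]
  res <- paste(out, collapse = "")
  if (grepl("U", x)) chartr("T", "U", res) else res
}

oracle_identity <- function(a, b, window) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  n <- 0L
  for (w in window) if (ac[w] == bc[w]) n <- n + 1L
  n
}

# overlapping occurrences of `pattern` in `subject` by sliding a window
oracle_count <- function(pattern, subject) {
  k <- nchar(pattern); n <- nchar(subject)
  if (n < k) return(0L)
  hits <- 0L
  for (i in 1:(n - k + 1)) if (substr(subject, i, i + k - 1) == pattern) hits <- hits + 1L
  hits
}

# own copy of the Xia/Turner WC dG37 stack constants for spreadsheet-style sums
oracle_nn <- c(AA = -0.93, UU = -0.93, AU = -1.10, UA = -1.33,
               CU = -2.08, AG = -2.08, CA = -2.11, UG = -2.11,
               GU = -2.24, AC = -2.24, GA = -2.35, UC = -2.35,
               CG = -2.36, GG = -3.26, CC = -3.26, GC = -3.42)

oracle_end_dG <- function(strand, partner, w = 4) {
  s <- strsplit(strand, "")[[1]]; p <- strsplit(partner, "")[[1]]
  L <- length(p)
  pairs <- c(A = "U", U = "A", G = "C", C = "G")
  ok <- sapply(1:w, function(i) identical(pairs[[s[i]]], p[L - i + 1]))
  total <- 0
  for (i in 1:(w - 1)) {
    if (ok[i] && ok[i + 1]) total <- total + oracle_nn[[paste0(s[i], s[i + 1])]]
  }
  total
}

random_rna_str <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                                    collapse = "")

# plant exactly k copies of `probe` (a DNA 7-mer) into random background,
# after wiping any accidental occurrences
plant_sites <- function(probe, k, bg_len = 300, seed = 1) {
  set.seed(seed)
  bg <- paste(sample(c("A", "C", "G", "T"), bg_len, replace = TRUE), collapse = "")
  while (oracle_count(probe, bg) > 0) {
    i <- regexpr(probe, bg, fixed = TRUE)
    substr(bg, i, i) <- sample(setdiff(c("A", "C", "G", "T"),
                                       substr(bg, i, i)), 1)
  }
  if (k == 0) return(bg)
  gap <- nchar(bg) %/% (k + 1)
  for (j in seq_len(k)) {
    at <- gap * j
    substr(bg, at, at + nchar(probe) - 1) <- probe
  }
  bg
}

fx <- paper_mirnas()
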