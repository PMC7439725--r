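# Position-weight-matrix scanning with an exact (discretised) null score
# distribution, plus readers/writers for MEME-minimal motif files and
# FIMO-style hit tables.

DNA_BASES <- c("A", "C", "G", "T")

check_pwm <- function(pwm) {
  if (!is.matrix(pwm) || nrow(pwm) != 4 ||
      is.null(rownames(pwm)) || !setequal(rownames(pwm), DNA_BASES)) {
    stop("malformed PWM: need a 4 x width matrix with rows A/C/G/T",
         call. = FALSE)
  }
  pwm <- pwm[DNA_BASES, , drop = FALSE]
  if (any(pwm < 0) || any(abs(colSums(pwm) - 1) > 1e-6)) {
    stop("malformed PWM: columns must be probabilities summing to 1",
         call. = FALSE)
  }
  pwm
}

# integer log-odds scores (vs uniform 0.25 background) on a 1/granularity
# lattice, plus the exact null distribution of the total integer score
pwm_score_table <- function(pwm, granularity = 1000) {
  pwm <- check_pwm(pwm)
  probs <- pmax(pwm, 1e-6)
  probs <- sweep(probs, 2, colSums(probs), "/")
  scores <- round(log2(probs / 0.25) * granularity)
  w <- ncol(scores)
  mins <- apply(scores, 2, min)
  shifted <- sweep(scores, 2, mins)                    # non-negative ints
  # convolve per-position score distributions (uniform background)
  dist <- 1
  for (j in seq_len(w)) {
    width_j <- max(shifted[, j])
    nd <- numeric(length(dist) + width_j)
    for (b in 1:4) {
      s <- shifted[b, j]
      nd[(s + 1):(s + length(dist))] <- nd[(s + 1):(s + length(dist))] +
        dist * 0.25
    }
    dist <- nd
  }
  # pval[k] = P(shifted total score >= k - 1)
  pval <- rev(cumsum(rev(dist)))
  list(scores = scores, shifted = shifted, shift = sum(mins),
       pval = pval, granularity = granularity)
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) {
           paste(rev(strsplit(s, "")[[1]]), collapse = "")
         }, character(1), USE.NAMES = FALSE))
}

#' Scan a sequence with a position weight matrix
#'
#' Log-odds scoring against a uniform 0.25 background on both strands.
#' Scores are discretised to a fixed lattice and the p-value of each
#' window is computed from the exact null distribution of the discretised
#' score (the convolution of the per-position score distributions); a
#' window is a hit when its p-value is at most `p_threshold`.
#'
#' @param sequence Nucleotide string (case-insensitive); windows
#'   containing non-ACGT symbols are skipped.
#' @param pwm 4 x width probability matrix with rows A/C/G/T.
#' @param p_threshold Hit p-value threshold (default 1e-4).
#' @return Data.frame `start` (1-based), `strand`, `score` (log2
#'   odds), `p`.
#' @export
scan_motifs <- function(sequence, pwm, p_threshold = 1e-4, .table = NULL) {
  tab <- if (is.null(.table)) pwm_score_table(pwm) else .table
  w <- ncol(tab$scores)
  seq_up <- toupper(sequence)
  if (nchar(seq_up) < w) {
    return(data.frame(start = integer(0), strand = character(0),
                      score = numeric(0), p = numeric(0)))
  }
  hits <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq_up else revcomp(seq_up)
    codes <- match(strsplit(s, "")[[1]], DNA_BASES)
    n <- length(codes)
    n_win <- n - w + 1
    # vectorised window scores: one indexed add per motif column
    sc <- numeric(n_win)
    valid <- rep(TRUE, n_win)
    for (j in seq_len(w)) {
      cj <- codes[j:(j + n_win - 1)]
      valid <- valid & !is.na(cj)
      cj[is.na(cj)] <- 1L
      sc <- sc + tab$shifted[cbind(cj, j)]
    }
    p <- tab$pval[sc + 1]
    hit <- valid & p <= p_threshold
    if (any(hit)) {
      i <- which(hit)
      start <- if (strand == "+") i else n - (i + w - 1) + 1L
      hits[[strand]] <- data.frame(
        start = start, strand = strand,
        score = (sc[i] + tab$shift) / tab$granularity, p = p[i],
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(start = integer(0), strand = character(0),
                      score = numeric(0), p = numeric(0)))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out[order(out$p, out$start), , drop = FALSE]
}

#' Scan many sequences with many motifs
#'
#' @param sequences Named character vector of sequences.
#' @param pwms Named list of PWMs.
#' @param p_threshold Per-window hit threshold.
#' @return FIMO-style data.frame: `motif_id`, `sequence_name`, `start`,
#'   `stop`, `strand`, `score`, `p.value`.
#' @export
scan_motif_set <- function(sequences, pwms, p_threshold = 1e-4) {
  rows <- list()
  for (m in names(pwms)) {
    w <- ncol(check_pwm(pwms[[m]]))
    tab <- pwm_score_table(pwms[[m]])
    for (s in names(sequences)) {
      h <- scan_motifs(sequences[[s]], pwms[[m]], p_threshold, .table = tab)
      if (nrow(h) > 0) {
        rows[[length(rows) + 1]] <- data.frame(
          motif_id = m, sequence_name = s, start = h$start,
          stop = h$start + w - 1L, strand = h$strand, score = h$score,
          p.value = h$p, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(motif_id = character(0), sequence_name = character(0),
                      start = integer(0), stop = integer(0),
                      strand = character(0), score = numeric(0),
                      p.value = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Collapse motif hits to a presence matrix
#'
#' @param hits FIMO-style hit table ([scan_motif_set()] or [read_fimo()]).
#' @param elements Element ids defining the rows (universe).
#' @param motifs Motif ids defining the columns; defaults to those seen.
#' @return Logical matrix elements x motifs.
#' @export
build_motif_matrix <- function(hits, elements, motifs = NULL) {
  if (is.null(motifs)) motifs <- sort(unique(hits$motif_id))
  m <- matrix(FALSE, length(elements), length(motifs),
              dimnames = list(elements, motifs))
  keep <- hits$sequence_name %in% elements & hits$motif_id %in% motifs
  if (any(keep)) {
    m[cbind(hits$sequence_name[keep], hits$motif_id[keep])] <- TRUE
  }
  m
}

#' Read motifs from a MEME-minimal motif file
#'
#' @param path File in MEME minimal format (`MOTIF` blocks with
#'   `letter-probability matrix` headers).
#' @return Named list of 4 x width probability matrices (rows A/C/G/T).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    if (grepl("^MOTIF\\s", lines[i])) {
      name <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
      j <- i + 1
      while (j <= length(lines) && !grepl("letter-probability matrix",
                                          lines[j])) {
        j <- j + 1
      }
      if (j > length(lines)) stop("malformed MEME file: missing matrix header",
                                  call. = FALSE)
      wm <- regmatches(lines[j], regexpr("w=\\s*\\d+", lines[j]))
      w <- as.integer(sub("w=\\s*", "", wm))
      rows <- lines[(j + 1):(j + w)]
      vals <- t(vapply(rows, function(r) {
        as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4])
      }, numeric(4), USE.NAMES = FALSE))
      pwm <- t(vals)
      rownames(pwm) <- DNA_BASES
      out[[name]] <- check_pwm(pwm)
      i <- j + w + 1
    } else {
      i <- i + 1
    }
  }
  if (length(out) == 0) stop("no motifs found in ", path, call. = FALSE)
  out
}

#' Write motifs to a MEME-minimal motif file
#'
#' @param pwms Named list of PWMs.
#' @param path Output path.
#' @export
write_meme <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (nm in names(pwms)) {
    pwm <- check_pwm(pwms[[nm]])
    writeLines(sprintf("MOTIF %s", nm), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                       ncol(pwm)), con)
    for (j in seq_len(ncol(pwm))) {
      writeLines(paste(sprintf("%.6f", pwm[, j]), collapse = " "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read a FIMO-style TSV hit table
#'
#' Accepts the tab-separated output of FIMO-like scanners; comment lines
#' starting with `#` are skipped. Column names are normalised to
#' `motif_id`, `sequence_name`, `start`, `stop`, `strand`, `score`,
#' `p.value`.
#'
#' @param path Path to the TSV.
#' @return Data.frame of hits.
#' @export
read_fimo <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  nm <- names(df)
  nm[nm %in% c("motif_alt_id")] <- "motif_alt_id"
  nm[nm %in% c("p-value", "pvalue")] <- "p.value"
  nm[nm %in% c("q-value", "qvalue")] <- "q.value"
  names(df) <- nm
  need <- c("motif_id", "sequence_name", "start", "stop", "strand",
            "score", "p.value")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("FIMO table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df[, intersect(c(need, "q.value", "matched_sequence"), names(df))]
}

#' Write a FIMO-style TSV hit table
#'
#' @param hits Hit table from [scan_motif_set()].
#' @param path Output path.
#' @export
write_fimo <- function(hits, path) {
  out <- hits
  names(out)[names(out) == "p.value"] <- "p-value"
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
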