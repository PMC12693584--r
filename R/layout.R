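#' Generate a random exon/intron genome layout
#'
#' Alternating intron/exon segments with exponentially distributed lengths
#' (minimum 1 bp), accumulated until the exonic target is reached; the
#' final exon is trimmed so the realized exonic length equals
#' `target_exonic` exactly, and a trailing intron closes the sequence.
#' Only exons receive tracked (nonsynonymous/synonymous) mutations;
#' introns act as recombination spacers, so the exon:intron ratio sets the
#' strength of linkage between selected sites. The defaults give roughly
#' one part exon to fourteen parts intron (1.4 Mb exonic in 21 Mb).
#'
#' @param mean_exon_len,mean_intron_len Mean segment lengths in bp;
#'   `mean_intron_len = 0` produces a single exon.
#' @param target_exonic Total exonic bp.
#' @param seed Optional integer seed.
#' @param exon_lengths,intron_lengths Optional empirical length tables
#'   (numeric vectors) sampled with replacement instead of the
#'   exponential draws.
#' @return A `genome_layout`: tibble of segments (`start`, `end`, `kind`;
#'   half-open 0-based coordinates) with attributes `total_length` and
#'   `exonic_length`.
#' @export
generate_layout <- function(mean_exon_len = 300, mean_intron_len = 4200,
                            target_exonic = 1.4e6, seed = NULL,
                            exon_lengths = NULL, intron_lengths = NULL) {
  if (!isTRUE(mean_exon_len > 0) && is.null(exon_lengths)) {
    stop("mean exon length must be positive")
  }
  if (!isTRUE(target_exonic > 0)) stop("target exonic length must be positive")
  with_seed(seed, {
    if (mean_intron_len == 0 && is.null(intron_lengths)) {
      segs <- tibble::tibble(start = 0, end = target_exonic, kind = "exon")
    } else {
      n_guess <- ceiling(target_exonic / mean_exon_len * 1.3) + 10L
      draw <- function(tbl, mean_len, k) {
        if (!is.null(tbl)) tbl[sample.int(length(tbl), k, replace = TRUE)]
        else pmax(1, round(rexp(k, 1 / mean_len)))
      }
      ex <- draw(exon_lengths, mean_exon_len, n_guess)
      while (sum(ex) < target_exonic) {
        ex <- c(ex, draw(exon_lengths, mean_exon_len, n_guess))
      }
      n_ex <- which(cumsum(ex) >= target_exonic)[1L]
      ex <- ex[seq_len(n_ex)]
      ex[n_ex] <- ex[n_ex] - (sum(ex) - target_exonic)
      intr <- draw(intron_lengths, mean_intron_len, n_ex + 1L)
      lens <- numeric(2L * n_ex + 1L)
      lens[c(TRUE, FALSE)] <- intr
      lens[c(FALSE, TRUE)] <- ex
      kind <- rep(c("intron", "exon"), length.out = 2L * n_ex + 1L)
      keep <- lens > 0
      ends <- cumsum(lens[keep])
      segs <- tibble::tibble(start = c(0, head(ends, -1L)), end = ends,
                             kind = kind[keep])
    }
    structure(segs, class = c("genome_layout", class(segs)),
              total_length = max(segs$end),
              exonic_length = sum(segs$end[segs$kind == "exon"] -
                                    segs$start[segs$kind == "exon"]))
  })
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("<genome_layout> %s bp total, %s bp exonic (%.3g%%), %d segments\n",
              format(attr(x, "total_length"), big.mark = ","),
              format(attr(x, "exonic_length"), big.mark = ","),
              100 * attr(x, "exonic_length") / attr(x, "total_length"),
              nrow(x)))
  NextMethod()
}

layout_exons <- function(layout) {
  ex <- layout[layout$kind == "exon", , drop = FALSE]
  list(starts = ex$start, ends = ex$end)
}
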