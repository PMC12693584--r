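#' Site-frequency spectrum container
#'
#' An SFS holds, for a sample of `n` haploid genomes, the number (or
#' expected number) of variant sites at each derived-allele count
#' `0, 1, ..., n`. Bins `0` and `n` are monomorphic and are excluded from
#' all likelihood and diversity computations; they are carried so that
#' observed and expected spectra share one container. Counts may be
#' real-valued so that model-expected spectra use the same type as tallied
#' data.
#'
#' @param counts Numeric vector of length `n + 1`, non-negative; entry `k + 1`
#'   is the number of sites with derived-allele count `k`.
#' @param n Haploid sample size. Defaults to `length(counts) - 1`.
#' @param L Callable sequence length (bp) this spectrum summarizes, or `NA`.
#' @param class_label One of `"synonymous"`, `"nonsynonymous"`, `"neutral"`,
#'   `"other"`.
#' @param folded Logical; this package's workflow uses unfolded spectra.
#' @return An object of class `sfs`.
#' @examples
#' sfs(c(0, 5, 3, 1, 0))
#' @export
sfs <- function(counts, n = length(counts) - 1L, L = NA_real_,
                class_label = "other", folded = FALSE) {
  counts <- as.numeric(counts)
  if (length(counts) != n + 1L) {
    stop("`counts` must have length n + 1 (got ", length(counts),
         " for n = ", n, ")")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("SFS counts must be finite and non-negative")
  }
  class_label <- match.arg(class_label,
                           c("synonymous", "nonsynonymous", "neutral", "other"))
  structure(
    list(counts = counts, n = as.integer(n), L = as.numeric(L),
         class_label = class_label, folded = isTRUE(folded)),
    class = "sfs"
  )
}

#' @export
print.sfs <- function(x, ...) {
  cat(sprintf("<sfs> n = %d, %s, %s, L = %s, %.6g segregating sites\n",
              x$n, if (x$folded) "folded" else "unfolded", x$class_label,
              if (is.na(x$L)) "NA" else format(x$L, big.mark = ","),
              segregating_sites(x)))
  print(x$counts, ...)
  invisible(x)
}

#' @export
as.data.frame.sfs <- function(x, ...) {
  data.frame(derived_count = 0:x$n, sites = x$counts)
}

#' @rdname sfs
#' @param x An `sfs` object.
#' @param ... Unused.
#' @export
as_tibble.sfs <- function(x, ...) {
  tibble::tibble(derived_count = 0:x$n, sites = x$counts,
                 class_label = x$class_label)
}

#' Number of segregating (polymorphic) sites in a spectrum
#'
#' @param x An `sfs`.
#' @return Sum of the polymorphic bins `1..n-1`.
#' @export
segregating_sites <- function(x) {
  stopifnot(inherits(x, "sfs"))
  sum(polymorphic(x))
}

#' Polymorphic bins of a spectrum
#'
#' The counts at derived-allele counts `1..n-1`, i.e. the part of the
#' spectrum that enters likelihoods and diversity statistics.
#'
#' @param x An `sfs`.
#' @return Numeric vector of length `n - 1`.
#' @export
polymorphic <- function(x) x$counts[seq(2L, x$n)]

#' Tally derived-allele counts into a site-frequency spectrum
#'
#' @param derived_counts Integer vector with one entry per site: the number
#'   of sampled haplotypes carrying the derived allele (each in `[0, n]`).
#'   Sites at `0` or `n` are monomorphic in the sample and land in the
#'   monomorphic bins.
#' @param n Haploid sample size.
#' @inheritParams sfs
#' @return An `sfs`.
#' @examples
#' tally_sfs(c(1, 1, 2), n = 4)
#' @export
tally_sfs <- function(derived_counts, n, L = NA_real_,
                      class_label = "other") {
  derived_counts <- as.integer(derived_counts)
  if (length(derived_counts) && (min(derived_counts) < 0L ||
                                 max(derived_counts) > n)) {
    stop("derived-allele counts must lie in [0, n]")
  }
  counts <- tabulate(derived_counts + 1L, nbins = n + 1L)
  sfs(counts, n = n, L = L, class_label = class_label)
}

#' Average pairwise differences (pi) from an unfolded spectrum
#'
#' Computes the total expected number of pairwise differences
#' \deqn{\pi = \sum_{i=1}^{n-1} X_i \, i (n - i) / \binom{n}{2},}
#' i.e. nucleotide diversity summed over the sequence the spectrum
#' represents (not per site). Monomorphic bins contribute zero.
#'
#' @param x An unfolded `sfs` with `n >= 2`.
#' @return Non-negative number.
#' @export
sfs_pi <- function(x) {
  stopifnot(inherits(x, "sfs"))
  if (x$folded) stop("pi from a folded spectrum is not supported")
  n <- x$n
  if (n < 2) stop("pi requires a sample of at least 2 haplotypes")
  i <- seq_len(n - 1L)
  sum(polymorphic(x) * i * (n - i)) / choose(n, 2)
}

#' Diversity reduction relative to the neutral expectation
#'
#' Compares observed diversity `pi` (from the spectrum) with the neutral
#' expectation `pi0 = 4 N mu L`. Their ratio quantifies the diversity
#' reduction caused by direct and linked (background) selection; it is near
#' 1 for a neutral class at equilibrium.
#'
#' @param x An unfolded `sfs`.
#' @param N Diploid population size.
#' @param mu Per-bp per-generation mutation rate.
#' @param L Sequence length in bp; defaults to the spectrum's `L` field.
#' @return A one-row tibble with columns `class`, `pi`, `pi0`, `ratio`.
#' @export
pi_ratio <- function(x, N, mu, L = x$L) {
  stopifnot(inherits(x, "sfs"))
  if (!isTRUE(N > 0) || !isTRUE(mu > 0) || !isTRUE(L > 0)) {
    stop("N, mu and L must all be positive")
  }
  pi <- sfs_pi(x)
  pi0 <- 4 * N * mu * L
  tibble::tibble(class = x$class_label, pi = pi, pi0 = pi0,
                 ratio = pi / pi0)
}

#' Sum spectra across independent simulation chunks
#'
#' Element-wise sum of spectra with identical sample size and folding;
#' sequence lengths add. Used to aggregate per-chunk spectra into one
#' replicate spectrum.
#'
#' @param ... `sfs` objects, or a single list of them.
#' @return An `sfs`.
#' @export
sum_sfs <- function(...) {
  spectra <- list(...)
  if (length(spectra) == 1L && !inherits(spectra[[1L]], "sfs")) {
    spectra <- spectra[[1L]]
  }
  stopifnot(length(spectra) >= 1L, all(vapply(spectra, inherits, TRUE, "sfs")))
  first <- spectra[[1L]]
  for (s in spectra[-1L]) {
    if (s$n != first$n) stop("spectra have mismatched sample sizes")
    if (s$folded != first$folded) stop("spectra have mismatched folding")
  }
  counts <- Reduce(`+`, lapply(spectra, `[[`, "counts"))
  Ls <- vapply(spectra, `[[`, 0.0, "L")
  sfs(counts, n = first$n, L = if (any(is.na(Ls))) NA_real_ else sum(Ls),
      class_label = first$class_label, folded = first$folded)
}

#' Fold a spectrum onto minor-allele counts
#'
#' Provided for completeness; the analyses in this package operate on
#' unfolded spectra (the simulator knows ancestral states).
#'
#' @param x An unfolded `sfs`.
#' @return A folded `sfs` of the same length with entries above `n/2` zero.
#' @export
fold_sfs <- function(x) {
  stopifnot(inherits(x, "sfs"), !x$folded)
  n <- x$n
  counts <- numeric(n + 1L)
  for (k in 0:n) {
    m <- min(k, n - k)
    counts[m + 1L] <- counts[m + 1L] + x$counts[k + 1L]
  }
  sfs(counts, n = n, L = x$L, class_label = x$class_label, folded = TRUE)
}

#' Read and write spectra in the "fs" text convention
#'
#' The format has a header line `"<n+1> <folded|unfolded>"` (extra tokens,
#' e.g. quoted population labels, are ignored), one whitespace-separated
#' line of `n + 1` values, and one mask line of `n + 1` 0/1 flags (1 =
#' masked). Comment lines starting with `#` are skipped. Writing always
#' masks the two monomorphic bins.
#'
#' @param path File path.
#' @param x An `sfs` to write.
#' @inheritParams sfs
#' @return `read_fs` returns an `sfs`; `write_fs` returns `x` invisibly.
#' @export
read_fs <- function(path, L = NA_real_, class_label = "other") {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(keep) < 3L) stop("fs file must have header, data and mask lines")
  header <- strsplit(trimws(lines[keep[1L]]), "\\s+")[[1L]]
  nbins <- suppressWarnings(as.integer(header[1L]))
  if (is.na(nbins) || nbins < 2L) {
    stop("fs parse error at line ", keep[1L], ": bad bin count '",
         header[1L], "'")
  }
  fold_tok <- intersect(header, c("folded", "unfolded"))
  if (length(fold_tok) != 1L) {
    stop("fs parse error at line ", keep[1L],
         ": header must contain 'folded' or 'unfolded'")
  }
  vals <- suppressWarnings(
    as.numeric(strsplit(trimws(lines[keep[2L]]), "\\s+")[[1L]]))
  if (length(vals) != nbins || any(is.na(vals))) {
    stop("fs parse error at line ", keep[2L], ": expected ", nbins,
         " numeric values, got ", length(vals))
  }
  mask <- suppressWarnings(
    as.integer(strsplit(trimws(lines[keep[3L]]), "\\s+")[[1L]]))
  if (length(mask) != nbins || any(is.na(mask)) || any(!mask %in% 0:1)) {
    stop("fs parse error at line ", keep[3L], ": expected ", nbins,
         " 0/1 mask values")
  }
  if (any(mask[-c(1L, nbins)] == 1L)) {
    warning("fs file masks interior bins; mask is recorded but counts kept")
  }
  sfs(vals, n = nbins - 1L, L = L, class_label = class_label,
      folded = fold_tok == "folded")
}

#' @rdname read_fs
#' @export
write_fs <- function(x, path) {
  stopifnot(inherits(x, "sfs"))
  mask <- integer(x$n + 1L)
  mask[c(1L, x$n + 1L)] <- 1L
  writeLines(c(
    paste(x$n + 1L, if (x$folded) "folded" else "unfolded"),
    paste(format(x$counts, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = " "),
    paste(mask, collapse = " ")
  ), path)
  invisible(x)
}
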