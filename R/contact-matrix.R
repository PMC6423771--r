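#' Binned intrachromosomal Hi-C contact matrix
#'
#' A `ContactMatrix` holds the symmetric, non-negative matrix of interaction
#' counts for one chromosome at one resolution, plus minimal metadata. Raw
#' matrices (`is_raw = TRUE`) carry integer counts; transformed matrices may
#' be real-valued. Only intrachromosomal maps are modelled: reproducibility
#' and quality scores are computed per chromosome.
#'
#' @param counts square symmetric numeric matrix of non-negative counts.
#' @param resolution bin width in base pairs.
#' @param chrom chromosome label.
#' @param is_raw logical; `TRUE` for integer count matrices.
#' @return an object of class `ContactMatrix` with fields `chrom`,
#'   `resolution`, `n_bins`, `counts`, `is_raw`.
#' @examples
#' m <- contact_matrix(matrix(c(3, 2, 2, 0), 2), resolution = 40000)
#' marginals(m)
#' total_interactions(m)
#' @export
contact_matrix <- function(counts, resolution, chrom = "chr1", is_raw = TRUE) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  dimnames(counts) <- NULL
  obj <- structure(
    list(chrom = as.character(chrom),
         resolution = as.numeric(resolution),
         n_bins = nrow(counts),
         counts = counts,
         is_raw = isTRUE(is_raw)),
    class = "ContactMatrix"
  )
  validate_contact_matrix(obj)
  obj
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix: %s, %d bins @ %g bp, %s counts, total %g\n",
              x$chrom, x$n_bins, x$resolution,
              if (x$is_raw) "raw integer" else "transformed",
              total_interactions(x)))
  invisible(x)
}

#' Validate a ContactMatrix
#'
#' Checks the structural invariants: square symmetric storage, finite
#' non-negative entries, integer counts when `is_raw`.
#'
#' @param m a `ContactMatrix`.
#' @return `m`, invisibly; errors if an invariant fails.
#' @export
validate_contact_matrix <- function(m) {
  if (!inherits(m, "ContactMatrix")) stop("not a ContactMatrix", call. = FALSE)
  cm <- m$counts
  if (!is.matrix(cm) || nrow(cm) != ncol(cm)) {
    stop("counts must be a square matrix", call. = FALSE)
  }
  if (m$n_bins != nrow(cm)) stop("n_bins does not match counts", call. = FALSE)
  if (anyNA(cm) || any(!is.finite(cm))) {
    stop("counts must be finite", call. = FALSE)
  }
  if (any(cm < 0)) stop("counts must be non-negative", call. = FALSE)
  if (!isTRUE(all.equal(cm, t(cm), tolerance = 1e-10, check.attributes = FALSE))) {
    stop("counts must be symmetric", call. = FALSE)
  }
  if (m$is_raw && any(cm != round(cm))) {
    stop("raw matrices must have integer counts", call. = FALSE)
  }
  if (!is.finite(m$resolution) || m$resolution <= 0) {
    stop("resolution must be a positive number of base pairs", call. = FALSE)
  }
  invisible(m)
}

#' Read a contact matrix from a text file
#'
#' Two plain-text layouts are supported. `triplet`: TAB-separated
#' `chrom start1 start2 count` rows with no header, one row per unordered
#' bin pair (upper triangle, `start1 <= start2`), bin start coordinates that
#' are multiples of the resolution, `#`-prefixed comment lines ignored.
#' Duplicate pairs are summed and every off-diagonal entry is mirrored.
#' `dense`: an `n_bins x n_bins` whitespace-separated numeric matrix.
#'
#' Files written by [write_contact_matrix()] carry a header comment that
#' records `n_bins`, so round-trips are exact even when trailing bins are
#' empty; foreign files without it infer `n_bins` from the largest
#' coordinate unless `chrom_length` is given.
#'
#' @param path file to read.
#' @param format `"triplet"` or `"dense"`.
#' @param resolution bin width in bp.
#' @param chrom_length optional chromosome length in bp; fixes
#'   `n_bins = ceiling(chrom_length / resolution)`.
#' @param chrom chromosome label override; for triplet files defaults to the
#'   label found in the file.
#' @param is_raw logical, whether entries are integer counts.
#' @return a [contact_matrix()].
#' @export
read_contact_matrix <- function(path, format = c("triplet", "dense"),
                                resolution, chrom_length = NULL,
                                chrom = NULL, is_raw = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  header <- parse_header_comment(path)
  if (format == "dense") {
    cm <- as.matrix(utils::read.table(path, header = FALSE, comment.char = "#"))
    dimnames(cm) <- NULL
    return(contact_matrix(cm, resolution,
                          chrom = chrom %||% header$chrom %||% "chr1",
                          is_raw = is_raw))
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  n_bins_known <- if (!is.null(chrom_length)) {
    as.integer(ceiling(chrom_length / resolution))
  } else {
    header$n_bins
  }
  if (length(lines) == 0) {
    if (is.null(n_bins_known)) {
      stop("empty triplet file and no chrom_length/header to size the matrix",
           call. = FALSE)
    }
    cm <- matrix(0, n_bins_known, n_bins_known)
    return(contact_matrix(cm, resolution,
                          chrom = chrom %||% header$chrom %||% "chr1",
                          is_raw = is_raw))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 4L)
  if (length(bad)) {
    stop(sprintf("malformed triplet row at line %d: expected 4 tab-separated fields",
                 bad[1]), call. = FALSE)
  }
  rec <- do.call(rbind, fields)
  file_chrom <- rec[1, 1]
  s1 <- as.numeric(rec[, 2]); s2 <- as.numeric(rec[, 3]); ct <- as.numeric(rec[, 4])
  if (anyNA(s1) || anyNA(s2) || anyNA(ct)) {
    stop("malformed triplet row: non-numeric coordinate or count", call. = FALSE)
  }
  if (any(ct < 0)) stop("negative count in triplet file", call. = FALSE)
  if (any(s1 %% resolution != 0) || any(s2 %% resolution != 0)) {
    stop("bin start is not a multiple of the resolution", call. = FALSE)
  }
  i <- s1 / resolution + 1L
  j <- s2 / resolution + 1L
  n <- n_bins_known %||% as.integer(max(i, j))
  if (max(i, j) > n) {
    stop("triplet coordinate beyond the stated chromosome length", call. = FALSE)
  }
  cm <- matrix(0, n, n)
  for (k in seq_along(i)) {
    cm[i[k], j[k]] <- cm[i[k], j[k]] + ct[k]
    if (i[k] != j[k]) cm[j[k], i[k]] <- cm[j[k], i[k]] + ct[k]
  }
  contact_matrix(cm, resolution, chrom = chrom %||% file_chrom, is_raw = is_raw)
}

#' Write a contact matrix to a text file
#'
#' Triplet files store the upper triangle only (`start1 <= start2`), one row
#' per non-zero unordered pair, preceded by a `#` header comment recording
#' chrom, resolution and `n_bins` so that [read_contact_matrix()]
#' round-trips exactly. Dense files store the full symmetric matrix as TSV.
#'
#' @param m a `ContactMatrix`.
#' @param path output file.
#' @param format `"triplet"` or `"dense"`.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(m, path, format = c("triplet", "dense")) {
  format <- match.arg(format)
  validate_contact_matrix(m)
  hdr <- sprintf("#hic3dqc chrom=%s resolution=%g n_bins=%d",
                 m$chrom, m$resolution, m$n_bins)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (format == "dense") {
    utils::write.table(m$counts, con, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  } else {
    idx <- which(upper.tri(m$counts, diag = TRUE) & m$counts != 0,
                 arr.ind = TRUE)
    if (nrow(idx)) {
      idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
      rows <- sprintf("%s\t%.15g\t%.15g\t%.15g", m$chrom,
                      (idx[, 1] - 1) * m$resolution,
                      (idx[, 2] - 1) * m$resolution,
                      m$counts[idx])
      writeLines(rows, con)
    }
  }
  invisible(path)
}

parse_header_comment <- function(path) {
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character())
  out <- list(chrom = NULL, n_bins = NULL)
  if (length(first) == 1 && startsWith(first, "#hic3dqc")) {
    kv <- regmatches(first, gregexpr("[a-z_]+=[^ ]+", first))[[1]]
    for (item in kv) {
      parts <- strsplit(item, "=", fixed = TRUE)[[1]]
      if (parts[1] == "chrom") out$chrom <- parts[2]
      if (parts[1] == "n_bins") out$n_bins <- as.integer(parts[2])
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-bin marginal totals
#'
#' The marginal of bin i is the sum of row i of the full symmetric matrix
#' (diagonal counted once). Marginals proxy the overall bias of a bin
#' (GC content, mappability) and drive the stratification of the
#' genomic-distance noise model and the bin sampling of the random-ligation
#' noise model.
#'
#' @param m a `ContactMatrix`.
#' @return numeric vector of length `n_bins`.
#' @export
marginals <- function(m) {
  validate_contact_matrix(m)
  rowSums(m$counts)
}

#' Total number of interactions
#'
#' Sum of counts over unordered bin pairs: the upper triangle including the
#' diagonal. This is the coverage N used by the noise model, downsampling
#' and pseudo-replicate construction.
#'
#' @param m a `ContactMatrix`.
#' @return a single number.
#' @export
total_interactions <- function(m) {
  validate_contact_matrix(m)
  (sum(m$counts) + sum(diag(m$counts))) / 2
}

# Upper-triangle (incl. diagonal) cell index helpers shared by the samplers.
# Cells are enumerated column-major over i <= j.
upper_cells <- function(n) {
  which(upper.tri(matrix(0, n, n), diag = TRUE))
}

# Rebuild a symmetric count matrix from upper-triangle cell values.
symmetrize_upper <- function(vals, n) {
  cm <- matrix(0, n, n)
  cm[upper_cells(n)] <- vals
  cm <- cm + t(cm)
  diag(cm) <- diag(cm) / 2
  cm
}
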