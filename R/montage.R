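#' Standard 64-channel scalp montage with grid coordinates
#'
#' A 10-10 style 64-electrode layout on a rectangular grid: rows run
#' anterior to posterior (Fp, AF, F, FC, C, CP, P, PO, O, I) and columns
#' follow the 10-10 numbering (z = midline, odd = left, even = right; labels
#' 1/2 sit one grid step out, 3/4 two steps, 5/6 three, 7/8 four, 9/10
#' five). On this grid the next-nearest electrode (two steps, ~6 cm on an
#' adult head) in each cardinal direction forms the Large-Laplacian
#' neighborhood of McFarland-type spatial filtering.
#'
#' @return data.frame with columns `label`, `row`, `col`.
#' @export
standard_montage <- function() {
  defs <- list(
    Fp = list(row = 0, cols = c(-1, 0, 1), prefix = "Fp"),
    AF = list(row = 1, cols = c(-4, -2, 0, 2, 4), prefix = "AF"),
    F  = list(row = 2, cols = c(-4, -3, -2, -1, 0, 1, 2, 3, 4), prefix = "F"),
    FC = list(row = 3, cols = c(-4, -3, -2, -1, 0, 1, 2, 3, 4), prefix = "FC"),
    C  = list(row = 4, cols = c(-4, -3, -2, -1, 0, 1, 2, 3, 4), prefix = "C"),
    CP = list(row = 5, cols = c(-4, -3, -2, -1, 0, 1, 2, 3, 4), prefix = "CP"),
    P  = list(row = 6, cols = c(-5, -4, -3, -2, -1, 0, 1, 2, 3, 4, 5), prefix = "P"),
    PO = list(row = 7, cols = c(-4, -2, 0, 2, 4), prefix = "PO"),
    O  = list(row = 8, cols = c(-1, 0, 1), prefix = "O"),
    I  = list(row = 9, cols = 0, prefix = "I")
  )
  col_label <- function(col) {
    if (col == 0) return("z")
    n <- abs(col)
    num <- if (col < 0) c(9, 7, 5, 3, 1)[6 - n] else c(10, 8, 6, 4, 2)[6 - n]
    as.character(num)
  }
  rows <- list()
  for (d in defs) {
    for (col in d$cols) {
      lab <- paste0(d$prefix, col_label(col))
      # conventional lateral names on the temporal line
      lab <- switch(lab, F9 = "F9", C7 = "T7", C8 = "T8",
                    FC7 = "FT7", FC8 = "FT8", CP7 = "TP7", CP8 = "TP8", lab)
      rows[[length(rows) + 1]] <- data.frame(label = lab, row = d$row, col = col)
    }
  }
  out <- do.call(rbind, rows)
  stopifnot(!anyDuplicated(out$label))
  rownames(out) <- NULL
  out
}

#' Large-Laplacian neighbor table
#'
#' For every montage electrode, the set of electrodes exactly two grid steps
#' away in the four cardinal directions (next-nearest neighbors). Edge
#' electrodes keep whichever of the four positions exist; electrodes with no
#' neighbor at all are reported with an empty set and excluded from
#' re-referencing by [laplacian_matrix()].
#'
#' @param montage data.frame from [standard_montage()] (or same shape).
#' @return named list mapping each label to a character vector of neighbors.
#' @export
laplacian_neighbors <- function(montage = standard_montage()) {
  key <- paste(montage$row, montage$col)
  out <- list()
  for (i in seq_len(nrow(montage))) {
    r <- montage$row[i]; c <- montage$col[i]
    cand <- paste(c(r - 2, r + 2, r, r), c(c, c, c - 2, c + 2))
    out[[montage$label[i]]] <- montage$label[match(cand, key, nomatch = 0)]
  }
  out
}

#' Large-Laplacian re-referencing matrix
#'
#' Builds the channels-by-channels linear operator `W` such that
#' `W %*% eeg` subtracts from each channel the mean of its next-nearest
#' neighbors. Channels absent from the montage (or with an empty neighbor
#' set) are passed through unchanged with a warning.
#'
#' @param labels channel labels of the recording, in matrix row order.
#' @param montage montage data.frame; defaults to [standard_montage()].
#' @return `length(labels)` square matrix.
#' @export
laplacian_matrix <- function(labels, montage = standard_montage()) {
  nb <- laplacian_neighbors(montage)
  n <- length(labels)
  W <- diag(n)
  dimnames(W) <- list(labels, labels)
  skipped <- character()
  for (i in seq_len(n)) {
    nbs <- intersect(nb[[labels[i]]], labels)
    if (length(nbs) == 0) {
      skipped <- c(skipped, labels[i])
      next
    }
    W[i, nbs] <- -1 / length(nbs)
  }
  if (length(skipped))
    warning("no Laplacian neighbors for channel(s): ",
            paste(skipped, collapse = ", "), "; passed through unfiltered")
  W
}
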