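## linear pixel indices grouped by label (excluding background 0)
label_index <- function(labels) {
  idx <- split(seq_along(labels), as.vector(labels))
  idx[names(idx) != "0"]
}

#' Derive nucleus / membrane-ring / cytosol compartments
#'
#' Splits every segmented cell into three disjoint compartments: the nucleus
#' (clipped to its cell), a membrane ring (the inner band of
#' `ring_width_px` pixels along the cell boundary, standing in for
#' plasma-membrane signal), and the cytosol (everything else). The three
#' masks partition the cell mask exactly; the image edge counts as cell
#' boundary for cells clipped by the field of view.
#'
#' Nuclei whose majority pixel does not fall inside any cell are dropped
#' with a warning.
#'
#' @param cell_labels integer label image of cells (0 = background).
#' @param nucleus_labels integer label image of nuclei.
#' @param ring_width_px width of the membrane ring in pixels (>= 0).
#' @return List with integer label images `nucleus`, `ring`, `cytosol`
#'   (labelled by cell id) and a `data.frame` `cells` mapping
#'   `cell` to `nucleus` label.
#' @export
derive_compartments <- function(cell_labels, nucleus_labels,
                                ring_width_px = 3) {
  stopifnot(all(dim(cell_labels) == dim(nucleus_labels)), ring_width_px >= 0)
  nr <- nrow(cell_labels)
  cell_idx <- label_index(cell_labels)
  nuc_idx <- label_index(nucleus_labels)

  ## map each nucleus to the cell that contains most of it
  nuc2cell <- integer(0)
  for (n in names(nuc_idx)) {
    tab <- table(cell_labels[nuc_idx[[n]]])
    best <- as.integer(names(tab)[which.max(tab)])
    if (best == 0) {
      warning("nucleus ", n, " lies outside all cells; dropped")
      next
    }
    nuc2cell[n] <- best
  }

  nuc_comp <- array(0L, dim = dim(cell_labels))
  ring <- array(0L, dim = dim(cell_labels))
  cyto <- array(0L, dim = dim(cell_labels))

  for (cname in names(cell_idx)) {
    cid <- as.integer(cname)
    lin <- cell_idx[[cname]]
    rr <- ((lin - 1L) %% nr) + 1L
    cc <- ((lin - 1L) %/% nr) + 1L
    r0 <- min(rr); r1 <- max(rr); c0 <- min(cc); c1 <- max(cc)
    h <- r1 - r0 + 1L; w <- c1 - c0 + 1L
    sub <- matrix(FALSE, h, w)
    loc <- cbind(rr - r0 + 1L, cc - c0 + 1L)
    sub[loc] <- TRUE
    ## pad so the image edge also counts as cell boundary
    pad <- matrix(0, h + 2, w + 2)
    pad[2:(h + 1), 2:(w + 1)] <- sub
    d <- as.matrix(EBImage::distmap(EBImage::Image(pad)))[
      2:(h + 1), 2:(w + 1), drop = FALSE]
    dist_v <- d[loc]

    my_nuc <- as.integer(names(nuc2cell)[nuc2cell == cid])
    is_nuc <- if (length(my_nuc))
      nucleus_labels[lin] %in% my_nuc else rep(FALSE, length(lin))
    is_ring <- !is_nuc & dist_v <= ring_width_px
    nuc_comp[lin[is_nuc]] <- cid
    ring[lin[is_ring]] <- cid
    cyto[lin[!is_nuc & !is_ring]] <- cid
  }

  cell_ids <- as.integer(names(cell_idx))
  cells <- data.frame(
    cell = cell_ids,
    nucleus = vapply(cell_ids, function(cid) {
      m <- which(nuc2cell == cid)
      if (length(m)) as.integer(names(nuc2cell)[m[1]]) else NA_integer_
    }, integer(1)))
  list(nucleus = nuc_comp, ring = ring, cytosol = cyto, cells = cells)
}
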