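## 384-well geometry: 16 rows (A..P) x 24 columns.
PLATE_ROWS <- 16L
PLATE_COLS <- 24L

#' Border (media) wells of a 384-well plate
#'
#' The outer ring of a 16x24 plate is filled with media to buffer
#' evaporation edge effects; these wells carry no cells.
#'
#' @return Character vector of the 76 border well ids.
#' @export
border_wells <- function() {
  idx <- expand.grid(row = seq_len(PLATE_ROWS), col = seq_len(PLATE_COLS))
  border <- idx$row == 1 | idx$row == PLATE_ROWS |
    idx$col == 1 | idx$col == PLATE_COLS
  well_id(idx$row[border], idx$col[border])
}

#' Build a 384-well screen plate layout
#'
#' Lays out one screening plate: the outer ring is media, control wells
#' (non-targeting, no-siRNA, PSENEN positive control, PLK1 cytotoxic
#' transfection control) and sample wells are placed on the 308 inner wells
#' by a seeded shuffle.
#'
#' @param n_sample_wells number of sample (gene knockdown) wells.
#' @param control_counts named integer vector of control well counts; names
#'   among `NT`, `no_siRNA`, `pos_ctrl_PSENEN`, `transfection_ctrl_PLK1`.
#'   Defaults to 8 NT and 4 of each other control.
#' @param condition `"NoEGTA"` or `"EGTA"`.
#' @param barcode plate barcode string.
#' @param replicate replicate index (the screen ran triplicates per
#'   condition).
#' @param genes optional character vector of gene symbols for the sample
#'   wells (length `n_sample_wells`); defaults to `gene0001`, ...
#' @param seed integer seed for the placement shuffle.
#' @return A `data.frame` with columns `well`, `row`, `col`, `role`, `gene`,
#'   `condition`, `barcode`, `replicate`; one row per well (384 rows).
#'   Unused inner wells have role `"empty"`.
#' @examples
#' lay <- make_plate_layout(100, condition = "NoEGTA", seed = 1)
#' table(lay$role)
#' @export
make_plate_layout <- function(n_sample_wells,
                              control_counts = c(NT = 8, no_siRNA = 4,
                                                 pos_ctrl_PSENEN = 4,
                                                 transfection_ctrl_PLK1 = 4),
                              condition = c("NoEGTA", "EGTA"),
                              barcode = "PLATE01", replicate = 1L,
                              genes = NULL, seed = 1L) {
  condition <- match.arg(condition)
  allowed <- c("NT", "no_siRNA", "pos_ctrl_PSENEN", "transfection_ctrl_PLK1")
  if (length(control_counts) && is.null(names(control_counts)))
    stop("control_counts must be named")
  bad <- setdiff(names(control_counts), allowed)
  if (length(bad)) stop("unknown control roles: ", paste(bad, collapse = ", "))

  idx <- expand.grid(row = seq_len(PLATE_ROWS), col = seq_len(PLATE_COLS))
  idx <- idx[order(idx$row, idx$col), ]
  border <- idx$row == 1 | idx$row == PLATE_ROWS |
    idx$col == 1 | idx$col == PLATE_COLS
  n_inner <- sum(!border)
  n_ctrl <- sum(control_counts)
  if (n_sample_wells + n_ctrl > n_inner)
    stop("capacity exceeded: ", n_sample_wells, " sample + ", n_ctrl,
         " control wells > ", n_inner, " inner wells")

  if (is.null(genes)) genes <- sprintf("gene%04d", seq_len(n_sample_wells))
  if (length(genes) != n_sample_wells)
    stop("genes must have length n_sample_wells")
  if (anyDuplicated(genes))
    stop("a gene may occupy at most one sample well per plate")

  role <- rep("media", nrow(idx))
  gene <- rep(NA_character_, nrow(idx))
  inner_pos <- which(!border)
  placed <- local_seed(seed, sample(inner_pos, n_sample_wells + n_ctrl))
  ctrl_roles <- rep(names(control_counts), times = control_counts)
  slots <- c(ctrl_roles, rep("sample", n_sample_wells))
  role[placed] <- slots
  gene[placed[slots == "sample"]] <- genes
  gene[role == "NT"] <- "NT"
  gene[role == "pos_ctrl_PSENEN"] <- "PSENEN"
  gene[role == "transfection_ctrl_PLK1"] <- "PLK1"
  role[role == "media" & !border] <- "empty"
  role[border] <- "media"

  data.frame(well = well_id(idx$row, idx$col), row = idx$row, col = idx$col,
             role = role, gene = gene, condition = condition,
             barcode = barcode, replicate = as.integer(replicate),
             stringsAsFactors = FALSE)
}

#' Validate a plate layout against screen conventions
#'
#' Checks the invariants a screening plate must satisfy: full 384-well
#' geometry, media on the entire outer ring, minimum control representation,
#' and no gene occupying more than one sample well.
#'
#' @param layout a layout `data.frame` from [make_plate_layout()].
#' @param min_nt,min_ctrl minimum NT and per-control-role well counts.
#' @return `TRUE` invisibly; stops with a message otherwise.
#' @export
validate_layout <- function(layout, min_nt = 8, min_ctrl = 4) {
  stopifnot(is.data.frame(layout))
  if (nrow(layout) != PLATE_ROWS * PLATE_COLS)
    stop("layout must have 384 wells")
  bw <- border_wells()
  if (!all(layout$role[layout$well %in% bw] == "media"))
    stop("all outer-ring wells must be media")
  if (sum(layout$role == "NT") < min_nt)
    stop("plate needs >= ", min_nt, " NT wells")
  for (r in c("no_siRNA", "pos_ctrl_PSENEN", "transfection_ctrl_PLK1"))
    if (sum(layout$role == r) < min_ctrl)
      stop("plate needs >= ", min_ctrl, " wells of role ", r)
  g <- layout$gene[layout$role == "sample"]
  if (anyDuplicated(g))
    stop("a gene occupies more than one sample well")
  invisible(TRUE)
}

#' Write / read a plate layout CSV
#'
#' Layouts are exchanged as plain CSV with columns
#' `well,row,col,role,gene,condition,barcode,replicate`.
#'
#' @param layout layout `data.frame`.
#' @param path file path.
#' @return `read_layout_csv` returns the layout `data.frame`.
#' @export
write_layout_csv <- function(layout, path) {
  utils::write.csv(layout, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_layout_csv
#' @export
read_layout_csv <- function(path) {
  if (!file.exists(path)) stop("layout file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
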