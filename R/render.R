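## Rendering constants (16-bit DN scale). Chosen to mimic a 20x widefield
## acquisition of MCF10A monolayers: dim uniform backgrounds, a bright
## peaked DAPI nuclear profile, moderate cytosolic phalloidin with bright
## cortical ridges, and a fixed per-cell NOTCH1 photon budget apportioned
## across compartments by the phenotype.
RENDER <- list(
  dapi_bg = 50, dapi_base = 1800, dapi_peak = 1400,
  dapi_texture_sd = 1.0, dapi_texture_scale = 0,
  phal_bg = 40, phal_cell = 400, phal_ridge = 2200,
  notch_bg = 5, notch_total = 3e5,
  spot_amplitude = 1500, spot_sigma = 1.5,
  nuc_r = c(6, 7), min_sep = 20, margin = 12, max_cell_radius = 30,
  ring_width = 3
)

#' Render one synthetic screen field with ground truth
#'
#' Draws a 3-channel fluorescence field (DAPI / phalloidin / NOTCH1) of
#' `n_cells` cells: non-overlapping elliptical nuclei, Voronoi-like cell
#' territories clipped at a maximum radius (leaving cell-free background
#' where seeds are distant), 2-px bright phalloidin ridges on shared
#' boundaries, and per-cell NOTCH1 signal split across membrane ring,
#' cytosol and nucleus according to `phenotype`, plus Poisson-distributed
#' Gaussian puncta in the cytosol. An optional Gaussian defocus blur is
#' applied to all channels before Poisson shot noise and Gaussian read
#' noise.
#'
#' @param phenotype a [phenotype_spec()].
#' @param n_cells number of cells to place (>= 0).
#' @param img_size integer c(rows, cols), each >= 128.
#' @param noise list with elements `gain` (DN per photon, default 1) and
#'   `read_sd` (Gaussian read noise SD in DN, default 10). Set both to
#'   `gain = 0` semantics is not supported; use `read_sd = 0` and
#'   `shot = FALSE` to disable noise.
#' @param shot logical; apply Poisson shot noise (default TRUE).
#' @param blur_sigma Gaussian defocus sigma in px (0 = in focus).
#' @param pixel_size_um pixel size (default 0.65 um at a 20x objective).
#' @param seed integer seed; identical seeds give identical fields.
#' @return An object of class `synthetic_field`: list with `channels`
#'   (named list of DAPI/phalloidin/NOTCH1 matrices), `bit_depth`,
#'   `pixel_size_um`, and `truth` (nucleus/cell label images, spot table,
#'   per-cell compartment signal sums, `blur_sigma`, `is_out_of_focus`).
#' @examples
#' f <- render_field(phenotype_presets()$NT, n_cells = 5,
#'                   img_size = c(128, 128), seed = 1)
#' range(f$channels$DAPI)
#' @export
render_field <- function(phenotype, n_cells,
                         img_size = c(256, 256),
                         noise = list(gain = 1, read_sd = 10),
                         shot = TRUE,
                         blur_sigma = 0, pixel_size_um = 0.65, seed = 1L) {
  stopifnot(inherits(phenotype, "phenotype_spec"), n_cells >= 0,
            length(img_size) == 2, all(img_size >= 128), blur_sigma >= 0)
  fr <- c(phenotype$pm_frac, phenotype$cyto_frac, phenotype$nuc_frac)
  if (abs(sum(fr) - 1) > 1e-9) stop("phenotype fractions must sum to 1")
  local_seed(seed, {
    nr <- img_size[1]; nc <- img_size[2]
    P <- RENDER

    ## --- nucleus centers: rejection sampling with minimum separation
    centers <- matrix(numeric(0), ncol = 2)
    tries <- 0
    while (nrow(centers) < n_cells && tries < n_cells * 300) {
      cand <- c(stats::runif(1, P$margin, nr - P$margin),
                stats::runif(1, P$margin, nc - P$margin))
      ok <- !nrow(centers) ||
        min(sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)) >=
        P$min_sep
      if (ok) centers <- rbind(centers, cand)
      tries <- tries + 1
    }
    n_placed <- nrow(centers)
    if (n_placed < n_cells)
      warning("placed ", n_placed, " of ", n_cells, " cells (field crowded)")

    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)

    ## --- Voronoi-like territories clipped at max_cell_radius
    cell_labels <- array(0L, dim = c(nr, nc))
    if (n_placed > 0) {
      best_d <- matrix(Inf, nr, nc)
      best_i <- matrix(0L, nr, nc)
      for (i in seq_len(n_placed)) {
        d2 <- (rows - centers[i, 1])^2 + (cols - centers[i, 2])^2
        upd <- d2 < best_d
        best_d[upd] <- d2[upd]
        best_i[upd] <- i
      }
      cell_labels <- best_i
      cell_labels[best_d > P$max_cell_radius^2] <- 0L
    }

    ## --- elliptical nuclei at cell centers, with chromatin texture
    ## (fine-scale multiplicative speckle: the structure that defocus
    ## destroys first, and what nuclear contrast QC keys on)
    nucleus_labels <- array(0L, dim = c(nr, nc))
    dapi <- matrix(P$dapi_bg, nr, nc)
    if (n_placed > 0) {
      tex <- matrix(stats::rnorm(nr * nc), nr, nc)
      if (P$dapi_texture_scale > 0)
        tex <- as.matrix(EBImage::gblur(EBImage::Image(tex),
                                        sigma = P$dapi_texture_scale))
      tex <- pmax(1 + P$dapi_texture_sd * (tex / stats::sd(tex)), 0.15)
      ab <- cbind(stats::runif(n_placed, P$nuc_r[1], P$nuc_r[2]),
                  stats::runif(n_placed, P$nuc_r[1], P$nuc_r[2]))
      th <- stats::runif(n_placed, 0, pi)
      for (i in seq_len(n_placed)) {
        dr <- rows - centers[i, 1]; dc <- cols - centers[i, 2]
        u <- (dr * cos(th[i]) + dc * sin(th[i])) / ab[i, 1]
        v <- (-dr * sin(th[i]) + dc * cos(th[i])) / ab[i, 2]
        rho2 <- u^2 + v^2
        m <- rho2 <= 1 & cell_labels == i
        nucleus_labels[m] <- i
        dapi[m] <- (P$dapi_base + P$dapi_peak * exp(-2 * rho2[m])) * tex[m]
      }
    }

    ## --- phalloidin: moderate cell fill + bright 2-px boundary ridges
    phal <- matrix(P$phal_bg, nr, nc)
    phal[cell_labels > 0] <- P$phal_cell
    if (n_placed > 0) {
      lab <- cell_labels
      diff_r <- lab[-1, ] != lab[-nr, ]
      diff_c <- lab[, -1] != lab[, -nc]
      ridge <- matrix(FALSE, nr, nc)
      ridge[-1, ][diff_r] <- TRUE; ridge[-nr, ][diff_r] <- TRUE
      ridge[, -1][diff_c] <- TRUE; ridge[, -nc][diff_c] <- TRUE
      ridge <- ridge & lab > 0
      phal[ridge] <- P$phal_ridge
    }

    ## --- NOTCH1: per-cell budget split across compartments + puncta
    notch <- matrix(P$notch_bg, nr, nc)
    spot_list <- list()
    comp <- NULL
    if (n_placed > 0) {
      comp <- derive_compartments(cell_labels, nucleus_labels,
                                  ring_width_px = P$ring_width)
      cell_idx <- label_index(cell_labels)
      ring_idx <- label_index(comp$ring)
      cyto_idx <- label_index(comp$cytosol)
      nuc_idx <- label_index(comp$nucleus)
      for (i in seq_len(n_placed)) {
        key <- as.character(i)
        parts <- list(pm = ring_idx[[key]], cyto = cyto_idx[[key]],
                      nuc = nuc_idx[[key]])
        fracs <- c(pm = phenotype$pm_frac, cyto = phenotype$cyto_frac,
                   nuc = phenotype$nuc_frac)
        for (k in names(parts)) {
          if (fracs[[k]] <= 0) next
          m <- parts[[k]]
          if (is.null(m) || !length(m))
            m <- cell_idx[[key]]  # degenerate compartment: whole cell
          notch[m] <- notch[m] + P$notch_total * fracs[[k]] / length(m)
        }
        ## cytosolic puncta
        k_sp <- stats::rpois(1, phenotype$spot_rate)
        cy <- parts$cyto
        if (k_sp > 0 && length(cy) > 0) {
          pick <- cy[sample.int(length(cy), k_sp, replace = TRUE)]
          for (s in seq_len(k_sp)) {
            sr <- ((pick[s] - 1L) %% nr) + 1L
            sc <- ((pick[s] - 1L) %/% nr) + 1L
            w <- 4L
            rr <- max(1, sr - w):min(nr, sr + w)
            cc <- max(1, sc - w):min(nc, sc + w)
            g <- outer((rr - sr)^2, (cc - sc)^2, "+")
            notch[rr, cc] <- notch[rr, cc] +
              P$spot_amplitude * exp(-g / (2 * P$spot_sigma^2))
            spot_list[[length(spot_list) + 1L]] <-
              data.frame(x = sc, y = sr, cell = i)
          }
        }
      }
    }
    spots <- if (length(spot_list)) do.call(rbind, spot_list) else
      data.frame(x = numeric(0), y = numeric(0), cell = integer(0))

    channels <- list(DAPI = dapi, phalloidin = phal, NOTCH1 = notch)
    if (blur_sigma > 0)
      channels <- lapply(channels, function(ch)
        as.matrix(EBImage::gblur(EBImage::Image(ch), sigma = blur_sigma)))

    ## truth compartment signal sums from the noiseless NOTCH1 channel
    comp_sums <- data.frame(cell = integer(0), pm_sum = numeric(0),
                            cyto_sum = numeric(0), nuc_sum = numeric(0),
                            total = numeric(0))
    if (n_placed > 0) {
      nt <- channels$NOTCH1
      sum_by <- function(lab) {
        s <- vapply(split(nt[lab > 0], as.vector(lab[lab > 0])), sum,
                    numeric(1))
        out <- numeric(n_placed)
        out[as.integer(names(s))] <- s
        out
      }
      comp_sums <- data.frame(cell = seq_len(n_placed),
                              pm_sum = sum_by(comp$ring),
                              cyto_sum = sum_by(comp$cytosol),
                              nuc_sum = sum_by(comp$nucleus),
                              total = sum_by(cell_labels))
    }

    ## camera model: Poisson shot noise + Gaussian read noise
    gain <- if (is.null(noise$gain)) 1 else noise$gain
    read_sd <- if (is.null(noise$read_sd)) 10 else noise$read_sd
    channels <- lapply(channels, function(ch) {
      v <- as.vector(ch)
      if (shot) v <- stats::rpois(length(v), v / gain) * gain
      if (read_sd > 0) v <- v + stats::rnorm(length(v), 0, read_sd)
      matrix(pmin(pmax(round(v), 0), 65535), nr, nc)
    })

    structure(list(
      channels = channels, bit_depth = 16L, pixel_size_um = pixel_size_um,
      truth = list(nucleus_labels = nucleus_labels,
                   cell_labels = cell_labels,
                   spots = spots, compartment_sums = comp_sums,
                   blur_sigma = blur_sigma,
                   is_out_of_focus = blur_sigma >= 3)
    ), class = "synthetic_field")
  })
}
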