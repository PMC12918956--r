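#' Render a fluorescence phantom with known compartment intensities
#'
#' Builds a synthetic fluorescence image of a small epithelial sheet with a
#' fully known ground truth: a bounded Voronoi cell layout, a junction band
#' of configurable width at the given junction intensity, cytoplasm and
#' nucleus compartments at their own levels, Gaussian puncta scattered in the
#' cytoplasm, and optional additive noise. All stored ground-truth metric
#' values (contrast ratio, cytoplasmic-to-nuclear ratio, puncta count and
#' density) are recomputable from the generation parameters.
#'
#' @param n_cells Number of cells in the layout.
#' @param box_um Field side (micrometres).
#' @param um_per_px Pixel size.
#' @param junction_width_px Junction band half-width (pixels).
#' @param junction_level,cytoplasm_level,nucleus_level Intensities.
#' @param nucleus_radius_um Nucleus disk radius; 0 disables nuclei.
#' @param n_puncta Number of puncta to place in the cytoplasm.
#' @param puncta_amplitude Peak amplitude added per punctum.
#' @param puncta_sigma_px Gaussian sigma of each punctum.
#' @param noise_sd Additive Gaussian noise SD.
#' @param background_margin_px Width of the zero-intensity background frame
#'   around the sheet (label 0), so that percentile-based background
#'   estimation behaves as on real images.
#' @param background_level Intensity of the background frame.
#' @param seed Integer seed.
#' @return List of class `phantom_image`: `image`, `labels`, `masks`
#'   (a [compartment_masks()]), `um_per_px`, `ground_truth` (levels, ratios,
#'   puncta table, density, `puncta_crowded` warning flag).
#' @export
render_fluorescence_phantom <- function(n_cells = 16L, box_um = 100,
                                        um_per_px = 0.5,
                                        junction_width_px = 2L,
                                        junction_level = 200,
                                        cytoplasm_level = 100,
                                        nucleus_level = 0,
                                        nucleus_radius_um = 0,
                                        n_puncta = 0L,
                                        puncta_amplitude = 150,
                                        puncta_sigma_px = 2,
                                        noise_sd = 0,
                                        background_margin_px = 6L,
                                        background_level = 0, seed = 1L) {
  n_px <- as.integer(round(box_um / um_per_px))
  with_seed(seed, {
    pos <- seed_positions(n_cells, box_um)
    labels <- rasterize_labels(pos[, 1L], pos[, 2L], seq_len(n_cells),
                               box_um, n_px, periodic = FALSE)
    if (background_margin_px > 0L) {
      m <- background_margin_px
      labels[c(seq_len(m), (n_px - m + 1L):n_px), ] <- 0L
      labels[, c(seq_len(m), (n_px - m + 1L):n_px)] <- 0L
    }
    masks <- compartment_masks(labels, um_per_px, junction_width_px,
                               nucleus_radius_um =
                                 if (nucleus_radius_um > 0) nucleus_radius_um
                                 else NULL)
    img <- matrix(background_level, n_px, n_px)
    img[masks$cytoplasm > 0] <- cytoplasm_level
    img[masks$junction > 0] <- junction_level
    img[masks$nucleus > 0] <- nucleus_level
    puncta <- data.frame(x_um = numeric(0), y_um = numeric(0),
                         row = integer(0), col = integer(0))
    crowded <- FALSE
    if (n_puncta > 0L) {
      cyto_idx <- which(masks$cytoplasm > 0, arr.ind = TRUE)
      # greedy placement keeping puncta at least min_separation_px apart;
      # if the cytoplasm is too crowded to honour that, the remainder is
      # placed unconstrained and flagged in the ground truth
      min_sep <- 3 * puncta_sigma_px
      ord <- sample.int(nrow(cyto_idx))
      pick <- matrix(0L, 0L, 2L)
      for (i in ord) {
        cand <- cyto_idx[i, , drop = FALSE]
        if (!nrow(pick) ||
            min((pick[, 1L] - cand[1L])^2 + (pick[, 2L] - cand[2L])^2) >=
            min_sep^2) {
          pick <- rbind(pick, cand)
        }
        if (nrow(pick) == n_puncta) break
      }
      if (nrow(pick) < n_puncta) {
        crowded <- TRUE
        warning("puncta exceed the separation capacity of the cytoplasm; ",
                "placing the remainder unconstrained")
        extra <- cyto_idx[sample.int(nrow(cyto_idx),
                                     n_puncta - nrow(pick)), , drop = FALSE]
        pick <- rbind(pick, extra)
      }
      rr <- matrix(rep(seq_len(n_px), n_px), n_px, n_px)
      cc <- matrix(rep(seq_len(n_px), each = n_px), n_px, n_px)
      for (i in seq_len(n_puncta)) {
        d2 <- (rr - pick[i, 1L])^2 + (cc - pick[i, 2L])^2
        img <- img + puncta_amplitude * exp(-d2 / (2 * puncta_sigma_px^2))
      }
      puncta <- data.frame(
        x_um = (pick[, 2L] - 0.5) * um_per_px,
        y_um = (n_px - pick[, 1L] + 0.5) * um_per_px,
        row = pick[, 1L], col = pick[, 2L])
    }
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(n_px * n_px, 0, noise_sd), n_px, n_px)
    }
    gt <- list(junction_level = junction_level,
               cytoplasm_level = cytoplasm_level,
               nucleus_level = nucleus_level,
               contrast_ratio = junction_level / cytoplasm_level,
               cyto_nuclear_ratio = if (nucleus_level > 0) {
                 cytoplasm_level / nucleus_level
               } else NA_real_,
               puncta = puncta, n_puncta = as.integer(n_puncta),
               puncta_density_per_um2 = n_puncta / box_um^2,
               puncta_crowded = crowded)
    structure(list(image = img, labels = labels, masks = masks,
                   um_per_px = um_per_px, ground_truth = gt),
              class = "phantom_image")
  })
}

#' @export
print.phantom_image <- function(x, ...) {
  cat(sprintf("phantom_image: %d x %d px (%g um/px), %d cells, %d puncta\n",
              nrow(x$image), ncol(x$image), x$um_per_px,
              length(setdiff(unique(as.vector(x$labels)), 0L)),
              x$ground_truth$n_puncta))
  invisible(x)
}
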