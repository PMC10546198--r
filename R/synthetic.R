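#' Parameters of a synthetic preterm retina
#'
#' Builds the parameter set consumed by [generate_retina()]. The model is a
#' circular fundus disc on a black background (as in smartphone fundus
#' photography through a condensing lens), with an optic-disc highlight,
#' radial vessels whose centerlines are sinusoidally perturbed (tortuosity),
#' an optional linear illumination gradient and saturated specular
#' highlights. Plus disease is emulated by larger tortuosity amplitude and
#' vessel caliber.
#'
#' @param image_side Side of the (square) image in pixels.
#' @param label `"no_plus"` or `"plus"`.
#' @param fundus_radius_frac Fundus radius as a fraction of the side; must be
#'   `< 0.5` so that the disc fits the frame.
#' @param n_vessels Number of radial vessels.
#' @param tortuosity_amp Peak lateral centerline displacement as a fraction
#'   of the vessel path length (dimensionless).
#' @param tortuosity_freq Sinusoid cycles per unit path length.
#' @param vessel_width Vessel full width in pixels at the optic disc
#'   (tapers to 40% at the periphery). Default scales with the fundus
#'   radius.
#' @param illumination_tilt Relative brightness change across the fundus
#'   (0 = flat lighting).
#' @param n_specular Number of saturated specular highlight blobs.
#' @param background_rgb Base fundus color (red, green, blue on `[0, 1]`).
#' @return A `retina_params` list.
#' @export
retina_params <- function(image_side = 640,
                          label = c("no_plus", "plus"),
                          fundus_radius_frac = 0.42,
                          n_vessels = 8,
                          tortuosity_amp = NULL,
                          tortuosity_freq = 2.5,
                          vessel_width = NULL,
                          illumination_tilt = 0.1,
                          n_specular = 1,
                          background_rgb = c(0.80, 0.45, 0.15)) {
  label <- match.arg(label)
  if (fundus_radius_frac >= 0.5)
    abort("`fundus_radius_frac` must be < 0.5 so the fundus disc fits in frame.",
          class = "fundusplus_parameter_error")
  if (fundus_radius_frac <= 0 || image_side < 64 || n_vessels < 0 ||
      illumination_tilt < 0 || n_specular < 0)
    abort("Invalid synthetic retina parameters.", class = "fundusplus_parameter_error")
  radius <- fundus_radius_frac * image_side
  if (is.null(tortuosity_amp))
    tortuosity_amp <- if (label == "plus") 0.045 else 0.015
  if (is.null(vessel_width))
    vessel_width <- (if (label == "plus") 0.022 else 0.014) * radius
  structure(list(
    image_side = as.integer(image_side), label = label,
    fundus_radius_frac = fundus_radius_frac, n_vessels = as.integer(n_vessels),
    tortuosity_amp = tortuosity_amp, tortuosity_freq = tortuosity_freq,
    vessel_width = vessel_width, illumination_tilt = illumination_tilt,
    n_specular = as.integer(n_specular),
    background_rgb = clamp01(background_rgb)
  ), class = "retina_params")
}

# class-conditional parameter draw using the current RNG state;
# effect_size scales the plus-vs-no_plus gap in tortuosity and caliber
draw_retina_params <- function(label, effect_size = 1,
                               side_range = c(300L, 1200L)) {
  side <- sample(seq.int(side_range[1], side_range[2]), 1L)
  frac <- runif(1, 0.35, 0.48)
  radius <- frac * side
  gap_amp <- 0.030 * effect_size
  gap_wid <- 0.008 * effect_size
  amp <- if (label == "plus") rnorm(1, 0.015 + gap_amp, 0.006)
         else rnorm(1, 0.015, 0.004)
  wfrac <- if (label == "plus") rnorm(1, 0.014 + gap_wid, 0.003)
           else rnorm(1, 0.014, 0.002)
  retina_params(
    image_side = side, label = label, fundus_radius_frac = frac,
    n_vessels = sample(6:12, 1L),
    tortuosity_amp = max(0.002, amp),
    tortuosity_freq = runif(1, 1.5, 3.5),
    vessel_width = max(0.004, wfrac) * radius,
    illumination_tilt = runif(1, 0, 0.25),
    n_specular = sample(0:3, 1L, prob = c(0.45, 0.30, 0.15, 0.10)),
    background_rgb = clamp01(c(0.80, 0.45, 0.15) + runif(3, -0.05, 0.05))
  )
}

#' Render a synthetic retina image
#'
#' Deterministically renders one labeled fundus image from a parameter set
#' and a seed. Vessels darken the green channel most strongly (mirroring the
#' high vessel-to-fundus contrast of the green channel in real fundus
#' photographs), every pixel outside the fundus disc is exactly zero, and
#' the vessel centerlines actually drawn are returned so that geometric
#' properties (e.g. [tortuosity_index()]) can be verified downstream.
#'
#' @param params A [retina_params()] object.
#' @param seed Integer seed; identical `(params, seed)` give bit-identical
#'   images.
#' @return A `synthetic_retina` list with elements `image` (H x W x 3 array
#'   on `[0, 1]`), `label`, `params`, `centerlines` (list of n x 2 matrices
#'   of (row, col) points, optic disc outward) and `fundus`
#'   (`center = c(row, col)`, `radius` in pixels).
#' @export
generate_retina <- function(params, seed) {
  if (!inherits(params, "retina_params"))
    abort("`params` must come from retina_params().",
          class = "fundusplus_parameter_error")
  withr::with_seed(as.integer(seed), {
    s <- params$image_side
    rad <- params$fundus_radius_frac * s
    cy <- s / 2 + runif(1, -0.03, 0.03) * s
    cx <- s / 2 + runif(1, -0.03, 0.03) * s
    yy <- matrix(seq_len(s), s, s)
    xx <- matrix(seq_len(s), s, s, byrow = TRUE)
    d <- sqrt((yy - cy)^2 + (xx - cx)^2)
    inside <- d <= rad

    shading <- 1 - 0.25 * (d / rad)^2
    phi <- runif(1, 0, 2 * pi)
    tilt <- 1 + params$illumination_tilt *
      (((yy - cy) * sin(phi) + (xx - cx) * cos(phi)) / rad)
    chans <- lapply(params$background_rgb, function(b) b * shading * tilt)

    # optic disc: bright yellowish blob offset from the fundus center
    od_ang <- runif(1, 0, 2 * pi)
    od_r <- 0.12 * rad
    ody <- cy + 0.25 * rad * sin(od_ang)
    odx <- cx + 0.25 * rad * cos(od_ang)
    dod <- sqrt((yy - ody)^2 + (xx - odx)^2)
    blob <- 0.85 * exp(-0.5 * dod^2 / (0.6 * od_r)^2)
    disc_col <- c(1.0, 0.85, 0.50)
    chans <- purrr::map2(chans, disc_col, function(ch, dc) ch + (dc - ch) * blob)

    # vessels: radial centerlines from the optic disc, sinusoidal lateral
    # perturbation of amplitude tortuosity_amp * path length
    centerlines <- list()
    vmask <- matrix(0, s, s)
    if (params$n_vessels > 0) {
      angs <- 2 * pi * (seq_len(params$n_vessels) - 1) / params$n_vessels +
        runif(params$n_vessels, -0.3, 0.3)
      for (v in seq_len(params$n_vessels)) {
        th <- angs[v]
        # ray-circle intersection: path length from optic disc to fundus rim
        oy <- ody - cy; ox <- odx - cx
        b <- oy * sin(th) + ox * cos(th)
        len <- -b + sqrt(max(0, b^2 - (oy^2 + ox^2 - rad^2)))
        if (len < 4) next
        t <- seq(0, len, by = 0.75)
        phase <- runif(1, 0, 2 * pi)
        amp_px <- params$tortuosity_amp * len
        off <- amp_px * sin(2 * pi * params$tortuosity_freq * t / len + phase) *
          sin(pi * t / len)  # pinned at both ends
        py <- ody + t * sin(th) + off * cos(th)
        px <- odx + t * cos(th) - off * sin(th)
        keep <- sqrt((py - cy)^2 + (px - cx)^2) <= rad - 1
        if (sum(keep) < 2) next
        py <- py[keep]; px <- px[keep]; tt <- t[keep]
        centerlines[[length(centerlines) + 1L]] <- cbind(row = py, col = px)
        width <- params$vessel_width * (1 - 0.6 * tt / len)
        vmask <- cpp_stamp_max(vmask, py, px, pmax(0.4, width / 2), rep(1, length(py)))
      }
    }
    dark <- c(0.30, 0.65, 0.15) # vessels darken green the most
    chans <- purrr::map2(chans, dark, function(ch, dk) ch * (1 - dk * vmask))

    # specular reflections: saturated white blobs inside the fundus
    if (params$n_specular > 0) {
      for (k in seq_len(params$n_specular)) {
        sa <- runif(1, 0, 2 * pi); sr <- runif(1, 0, 0.8) * rad
        sy <- cy + sr * sin(sa); sx <- cx + sr * cos(sa)
        srad <- runif(1, 0.02, 0.05) * rad
        dsp <- sqrt((yy - sy)^2 + (xx - sx)^2)
        spec <- exp(-0.5 * dsp^2 / (srad / 1.5)^2)
        chans <- lapply(chans, function(ch) ch + (1 - ch) * spec)
      }
    }

    img <- array(0, c(s, s, 3))
    for (k in 1:3) img[, , k] <- clamp01(chans[[k]]) * inside
    structure(list(image = img, label = params$label, params = params,
                   centerlines = centerlines,
                   fundus = list(center = c(cy, cx), radius = rad)),
              class = "synthetic_retina")
  })
}

#' @export
print.synthetic_retina <- function(x, ...) {
  cat(sprintf("<synthetic_retina> %dx%d, label %s, %d vessels, fundus r=%.0f px\n",
              x$params$image_side, x$params$image_side, x$label,
              length(x$centerlines), x$fundus$radius))
  invisible(x)
}

#' Tortuosity index of a vessel centerline
#'
#' Arc length divided by chord length; 1 for a straight segment, larger for
#' more tortuous vessels. This is the standard geometric tortuosity measure
#' used to verify that the generator's plus-disease class is rendered with
#' more tortuous vessels.
#'
#' @param line An n x 2 numeric matrix of ordered centerline points
#'   (n >= 2), or something coercible to one.
#' @return A scalar `>= 1`.
#' @export
tortuosity_index <- function(line) {
  line <- as.matrix(line)
  if (nrow(line) < 2 || !all(is.finite(line)))
    abort("Centerline needs at least 2 finite points.",
          class = "fundusplus_degenerate_error")
  seg <- sqrt(rowSums(diff(line)^2))
  chord <- sqrt(sum((line[nrow(line), ] - line[1, ])^2))
  if (chord < .Machine$double.eps)
    abort("Coincident endpoints: tortuosity undefined.",
          class = "fundusplus_degenerate_error")
  max(1, sum(seg) / chord)
}

#' Generate a labeled synthetic cohort
#'
#' Draws per-image parameters from class-conditional distributions that
#' mirror the smartphone screening setting: image sides uniform on
#' `[300, 1200]` px, variable lighting with occasional specular highlights,
#' and (by default) heavy class imbalance. Plus-class draws have larger
#' tortuosity amplitude and vessel width by `effect_size`.
#'
#' @param n_no_plus,n_plus Class counts.
#' @param seed Master seed; the whole cohort is reproducible from it.
#' @param effect_size Multiplier on the class gap of the tortuosity and
#'   caliber distributions (1 = default gap; 0 = identical classes).
#' @param render If `FALSE`, only parameters and labels are drawn (fast;
#'   useful for split/plumbing work at the full 385/55 scale).
#' @param side_range Integer range the image side is sampled from.
#' @return A tibble with columns `id`, `label`, `image_side`, `seed`,
#'   `params` (list), and when rendered `image`, `centerlines`, `fundus`
#'   list-columns.
#' @export
generate_cohort <- function(n_no_plus, n_plus, seed, effect_size = 1,
                            render = TRUE, side_range = c(300L, 1200L)) {
  if (n_no_plus < 0 || n_plus < 0)
    abort("Counts must be >= 0.", class = "fundusplus_parameter_error")
  n <- n_no_plus + n_plus
  labels <- c(rep("no_plus", n_no_plus), rep("plus", n_plus))
  if (n == 0)
    return(tibble::tibble(id = character(), label = as_plus_factor(character()),
                          image_side = integer(), seed = integer(),
                          params = list()))
  params <- withr::with_seed(as.integer(seed), {
    lapply(labels, draw_retina_params, effect_size = effect_size,
           side_range = side_range)
  })
  seeds <- derive_seeds(as.integer(seed) + 1L, n)
  out <- tibble::tibble(
    id = sprintf("img%04d", seq_len(n)),
    label = as_plus_factor(labels),
    image_side = vapply(params, function(p) p$image_side, integer(1)),
    seed = seeds,
    params = params
  )
  if (render) {
    ren <- purrr::map2(params, seeds, generate_retina)
    out$image <- purrr::map(ren, "image")
    out$centerlines <- purrr::map(ren, "centerlines")
    out$fundus <- purrr::map(ren, "fundus")
  }
  out
}
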