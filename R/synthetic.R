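# Synthetic multichannel micrograph generator. Scenes plant Fourier-perturbed
# elliptical nuclei with optional micronuclei, NE blebs (dimmer DNA, lamin-B
# gap, lamin-A/C enrichment) and intranuclear lamin-B tubes (invaginations),
# render them with 4x supersampling, add Gaussian (and optional Poisson)
# noise, and emit a ground-truth table with per-object pixel masks.

#' Specification of a synthetic scene
#'
#' All geometric parameters are in final-resolution pixels; intensity levels
#' are arbitrary raw units. `snr`, reported for convenience, is
#' `dna_level / noise_sd`.
#'
#' @param width,height image size in px.
#' @param n_nuclei number of nuclei (placed on a jittered grid; an error is
#'   raised if they cannot be packed).
#' @param radius_range min/max base nucleus radius.
#' @param aspect_range min/max axis ratio of the base ellipse.
#' @param lobe_orders angular orders of the radius perturbation.
#' @param lobe_amp maximum relative amplitude per order (0 = perfect
#'   ellipses, with closed-form descriptor truth).
#' @param micronucleus_prob probability a nucleus carries one micronucleus.
#' @param mn_ratio_range micronucleus/nucleus equivalent-diameter ratio range.
#' @param mn_gap_range gap between nucleus boundary and micronucleus rim, px.
#' @param mn_dna_frac micronucleus DNA level relative to the nucleus.
#' @param bleb_prob probability a nucleus carries one bleb.
#' @param bleb_radius_range bleb (hemispherical protrusion) radius range, px.
#' @param bleb_dna_frac DNA level in the bleb relative to the nucleus (< 1:
#'   blebs contain less DNA).
#' @param bleb_lamin_gap interrupt the lamin-B ring at the bleb neck.
#' @param bleb_chromatin render DNA inside the bleb (FALSE gives a
#'   membrane-only bleb, invisible to the subtraction method).
#' @param bleb_lac_enrich target raw-intensity lamin-A/C enrichment of the
#'   bleb over the nuclear body (background included in both means).
#' @param invag_count_range min/max number of planted invagination tubes per
#'   nucleus (parallel non-crossing chords).
#' @param tube_width invagination tube width, px.
#' @param ring_width lamin-B ring width, px.
#' @param lamin_interior_frac diffuse nucleoplasmic lamin-B level as a
#'   fraction of the ring level (lamin B1 staining shows a nucleoplasmic
#'   pool besides the NE rim; makes the thresholded lamin object solid).
#' @param dna_level,lamin_level,lac_level,background channel intensity levels.
#' @param noise_sd Gaussian noise standard deviation (0 = off).
#' @param poisson apply Poisson shot noise before the Gaussian component.
#' @param supersample sub-pixel rendering factor (box down-sampling).
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(width = 768L, height = 768L, n_nuclei = 25L,
                       radius_range = c(34, 46), aspect_range = c(1, 1.4),
                       lobe_orders = 2:4, lobe_amp = 0.04,
                       micronucleus_prob = 0,
                       mn_ratio_range = c(0.15, 0.25),
                       mn_gap_range = c(4, 14), mn_dna_frac = 0.9,
                       bleb_prob = 0, bleb_radius_range = c(6, 7),
                       bleb_dna_frac = 0.6, bleb_lamin_gap = TRUE,
                       bleb_chromatin = TRUE, bleb_lac_enrich = 1.5,
                       invag_count_range = c(0, 0), tube_width = 3.5,
                       ring_width = 3, lamin_interior_frac = 0.45,
                       dna_level = 100, lamin_level = 120, lac_level = 80,
                       background = 10, noise_sd = 20, poisson = FALSE,
                       supersample = 4L) {
  spec <- as.list(environment())
  chk <- function(ok, what) if (!ok) stop("invalid scene spec: ", what)
  chk(width >= 64 && height >= 64, "image too small")
  chk(n_nuclei >= 1, "need at least one nucleus")
  chk(all(radius_range > 0) && diff(radius_range) >= 0, "bad radius_range")
  chk(all(aspect_range >= 1), "aspect_range must be >= 1")
  chk(lobe_amp >= 0 && lobe_amp < 0.3, "lobe_amp must be in [0, 0.3)")
  chk(micronucleus_prob >= 0 && micronucleus_prob <= 1, "bad micronucleus_prob")
  chk(bleb_prob >= 0 && bleb_prob <= 1, "bad bleb_prob")
  chk(all(mn_ratio_range > 0 & mn_ratio_range < 1), "bad mn_ratio_range")
  chk(all(invag_count_range >= 0), "bad invag_count_range")
  chk(tube_width > 0 && ring_width > 0, "widths must be positive")
  chk(lamin_interior_frac >= 0 && lamin_interior_frac < 1,
      "lamin_interior_frac must be in [0,1)")
  chk(all(c(dna_level, lamin_level, lac_level) > 0), "levels must be positive")
  chk(background >= 0 && noise_sd >= 0, "background/noise must be >= 0")
  chk(supersample >= 1, "supersample must be >= 1")
  spec$snr <- if (noise_sd > 0) dna_level / noise_sd else Inf
  structure(spec, class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(paste0("<scene_spec> %dx%d px, %d nuclei, SNR %.3g\n",
                     "  P(micronucleus)=%.2f P(bleb)=%.2f invaginations %d-%d\n"),
              x$width, x$height, x$n_nuclei, x$snr,
              x$micronucleus_prob, x$bleb_prob,
              x$invag_count_range[1], x$invag_count_range[2]))
  invisible(x)
}

# box down-sampling of a supersampled block (S^2 subpixels per final pixel)
box_downsample <- function(m, S) {
  if (S == 1L) return(m)
  nr <- nrow(m) / S; nc <- ncol(m) / S
  ri <- rep(seq_len(nr), each = S)
  ci <- rep(seq_len(nc), each = S)
  t(rowsum(t(rowsum(m, ri)), ci)) / S^2
}

#' Render a synthetic scene
#'
#' Deterministic for a fixed spec and seed (bit-identical images). The DNA
#' channel fills nuclei at full level and blebs at the stated fraction;
#' the lamin-B channel is a ring along each nuclear contour, interrupted at
#' bleb necks, plus intranuclear tubes for planted invaginations; the
#' lamin-A/C channel fills the nucleus and is enriched in blebs. Micronuclei
#' are DNA-positive disks in the cell territory near their nucleus.
#'
#' @param spec a [scene_spec()].
#' @param seed integer seed driving all stochastic choices.
#' @return list with `channels` (named list of [channel_image()]: `dna`,
#'   `laminB`, `laminAC`), `truth` (data.frame of planted objects) and
#'   `masks` (list of pre-noise pixel-index masks, one per truth row,
#'   coverage >= 0.5).
#' @export
render_scene <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "scene_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  W <- spec$width; H <- spec$height; S <- spec$supersample
  rmax <- spec$radius_range[2] * sqrt(spec$aspect_range[2]) *
    (1 + length(spec$lobe_orders) * spec$lobe_amp)
  reach <- rmax + 2 +
    (spec$bleb_prob > 0) * spec$bleb_radius_range[2] +
    (spec$micronucleus_prob > 0) *
      (spec$mn_gap_range[2] + spec$mn_ratio_range[2] * rmax)
  ncx <- ceiling(sqrt(spec$n_nuclei * W / H))
  ncy <- ceiling(spec$n_nuclei / ncx)
  cw <- W / ncx; ch <- H / ncy
  if (min(cw, ch) / 2 < reach + 1)
    stop("infeasible packing: ", spec$n_nuclei, " nuclei with reach ",
         round(reach, 1), " px do not fit in ", W, "x", H)
  jit <- max(0, min(cw, ch) / 2 - reach - 1)
  jit <- min(jit, 12)
  dna <- matrix(0, H, W); lamb <- matrix(0, H, W); lac <- matrix(0, H, W)
  truth <- list(); masks <- list()
  add_obj <- function(row) {
    truth[[length(truth) + 1L]] <<- row
  }
  cells <- expand.grid(iy = seq_len(ncy), ix = seq_len(ncx))
  for (i in seq_len(spec$n_nuclei)) {
    cyx <- cells[i, ]
    ctr_r <- (cyx$iy - 0.5) * ch + stats::runif(1, -jit, jit)
    ctr_c <- (cyx$ix - 0.5) * cw + stats::runif(1, -jit, jit)
    r0 <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
    q <- stats::runif(1, spec$aspect_range[1], spec$aspect_range[2])
    phi <- stats::runif(1, 0, pi)
    amps <- stats::runif(length(spec$lobe_orders), 0, spec$lobe_amp)
    phs <- stats::runif(length(spec$lobe_orders), 0, 2 * pi)
    a <- r0 * sqrt(q); b <- r0 / sqrt(q)
    rfun <- function(theta) {
      u <- theta - phi
      re <- a * b / sqrt((b * cos(u))^2 + (a * sin(u))^2)
      pert <- 1 + as.numeric(cos(outer(theta, spec$lobe_orders) +
                                   rep(phs, each = length(theta))) %*% amps)
      re * pert
    }
    has_bleb <- stats::runif(1) < spec$bleb_prob
    bleb_theta <- stats::runif(1, 0, 2 * pi)
    bleb_r <- stats::runif(1, spec$bleb_radius_range[1],
                           spec$bleb_radius_range[2])
    has_mn <- stats::runif(1) < spec$micronucleus_prob
    mn_theta <- stats::runif(1, 0, 2 * pi)
    if (has_bleb && has_mn) {
      # keep the micronucleus away from the bleb sector
      while (abs(((mn_theta - bleb_theta + pi) %% (2 * pi)) - pi) < pi / 3)
        mn_theta <- stats::runif(1, 0, 2 * pi)
    }
    inv_rng <- spec$invag_count_range
    n_inv <- if (inv_rng[2] > inv_rng[1])
      sample(inv_rng[1]:inv_rng[2], 1L) else as.integer(inv_rng[1])
    inv_phi <- stats::runif(1, 0, pi)
    inv_off <- numeric(0)
    if (n_inv > 0) {
      # parallel non-crossing chords: an evenly spaced comb, jittered as a
      # whole so the inter-tube gaps stay wide enough to remain separable
      span <- 0.66 * r0
      base <- seq(-span, span, length.out = n_inv + 2L)[2:(n_inv + 1L)]
      inv_off <- base + stats::runif(1, -1, 1)
    }
    # ---- supersampled rendering in the nucleus bounding box ----
    ext <- ceiling(rmax + 2 + if (has_bleb) bleb_r + 1 else 0)
    rr0 <- max(1L, floor(ctr_r - ext)); rr1 <- min(H, ceiling(ctr_r + ext))
    cc0 <- max(1L, floor(ctr_c - ext)); cc1 <- min(W, ceiling(ctr_c + ext))
    nrf <- rr1 - rr0 + 1L; ncf <- cc1 - cc0 + 1L
    rsub <- rr0 - 0.5 + (seq_len(nrf * S) - 0.5) / S
    csub <- cc0 - 0.5 + (seq_len(ncf * S) - 0.5) / S
    dy <- matrix(rsub - ctr_r, nrf * S, ncf * S)
    dx <- matrix(csub - ctr_c, nrf * S, ncf * S, byrow = TRUE)
    rho <- sqrt(dx^2 + dy^2)
    theta <- atan2(dy, dx)
    Rb <- matrix(rfun(as.numeric(theta)), nrf * S, ncf * S)
    body <- rho <= Rb
    ring <- body & rho > (Rb - spec$ring_width)
    blebm <- matrix(FALSE, nrf * S, ncf * S)
    ring_keep <- ring
    if (has_bleb) {
      # centre the bleb disk slightly outside the boundary: blebs balloon
      # outward through the lamina gap rather than sitting half-embedded
      rho_b <- rfun(bleb_theta) + 0.3 * bleb_r
      bcr <- ctr_r + rho_b * sin(bleb_theta)
      bcc <- ctr_c + rho_b * cos(bleb_theta)
      blebm <- (dx - (bcc - ctr_c))^2 + (dy - (bcr - ctr_r))^2 <= bleb_r^2 &
        !body
      if (spec$bleb_lamin_gap) {
        gam <- atan(bleb_r / rho_b) * 1.2
        dth <- abs(((theta - bleb_theta + pi) %% (2 * pi)) - pi)
        ring_keep <- ring & dth > gam
      }
    }
    tubes <- vector("list", n_inv)
    if (n_inv > 0) {
      dperp <- -dx * sin(inv_phi) + dy * cos(inv_phi)
      for (t in seq_len(n_inv)) {
        tubes[[t]] <- abs(dperp - inv_off[t]) <= spec$tube_width / 2 &
          rho <= Rb - 0.5
      }
    }
    tube_any <- if (n_inv > 0) Reduce(`|`, tubes) else
      matrix(FALSE, nrf * S, ncf * S)
    dna_sub <- spec$dna_level * body
    if (has_bleb && spec$bleb_chromatin)
      dna_sub <- dna_sub + spec$bleb_dna_frac * spec$dna_level * blebm
    lam_struct <- ring_keep | tube_any
    lam_sub <- spec$lamin_level * lam_struct +
      spec$lamin_interior_frac * spec$lamin_level * (body & !lam_struct)
    lac_sub <- spec$lac_level * body
    if (has_bleb) {
      # bleb level chosen so the *raw* mean ratio (background included)
      # equals bleb_lac_enrich
      lvl <- max(0, spec$bleb_lac_enrich * (spec$lac_level + spec$background) -
                   spec$background)
      lac_sub <- lac_sub + lvl * blebm
    }
    rows <- rr0:rr1; colsr <- cc0:cc1
    dna[rows, colsr] <- dna[rows, colsr] + box_downsample(dna_sub, S)
    lamb[rows, colsr] <- lamb[rows, colsr] + box_downsample(lam_sub, S)
    lac[rows, colsr] <- lac[rows, colsr] + box_downsample(lac_sub, S)
    to_idx <- function(covmat) {
      w <- which(covmat >= 0.5, arr.ind = TRUE)
      (cc0 - 1L + w[, 2] - 1L) * H + (rr0 - 1L + w[, 1])
    }
    body_cov <- box_downsample(body + 0, S)
    add_obj(data.frame(kind = "nucleus", id = NA_integer_, nucleus_id = i,
                       center_row = ctr_r, center_col = ctr_c,
                       radius = r0, aspect = q, orientation = phi,
                       lobe_amp_total = sum(amps),
                       analytic_eccentricity = if (spec$lobe_amp == 0)
                         sqrt(1 - (b / a)^2) else NA_real_,
                       analytic_area = if (spec$lobe_amp == 0) pi * a * b
                         else NA_real_,
                       dna_frac = 1))
    masks[[length(masks) + 1L]] <- to_idx(body_cov)
    if (has_bleb) {
      add_obj(data.frame(kind = "bleb", id = NA_integer_, nucleus_id = i,
                         center_row = bcr, center_col = bcc,
                         radius = bleb_r, aspect = NA_real_,
                         orientation = bleb_theta, lobe_amp_total = NA_real_,
                         analytic_eccentricity = NA_real_,
                         analytic_area = NA_real_,
                         dna_frac = if (spec$bleb_chromatin)
                           spec$bleb_dna_frac else 0))
      masks[[length(masks) + 1L]] <- to_idx(box_downsample(blebm + 0, S))
    }
    if (n_inv > 0) {
      for (t in seq_len(n_inv)) {
        add_obj(data.frame(kind = "invagination", id = NA_integer_,
                           nucleus_id = i, center_row = ctr_r,
                           center_col = ctr_c, radius = spec$tube_width / 2,
                           aspect = NA_real_, orientation = inv_phi,
                           lobe_amp_total = inv_off[t],
                           analytic_eccentricity = NA_real_,
                           analytic_area = NA_real_, dna_frac = NA_real_))
        masks[[length(masks) + 1L]] <- to_idx(box_downsample(tubes[[t]] + 0, S))
      }
    }
    if (has_mn) {
      ratio <- stats::runif(1, spec$mn_ratio_range[1], spec$mn_ratio_range[2])
      # nucleus equivalent diameter 2*sqrt(a*b) for the base ellipse
      mnr <- ratio * sqrt(a * b)
      gap <- stats::runif(1, spec$mn_gap_range[1], spec$mn_gap_range[2])
      dctr <- rfun(mn_theta) + gap + mnr
      mcr <- ctr_r + dctr * sin(mn_theta)
      mcc <- ctr_c + dctr * cos(mn_theta)
      me <- ceiling(mnr + 2)
      mr0 <- max(1L, floor(mcr - me)); mr1 <- min(H, ceiling(mcr + me))
      mc0 <- max(1L, floor(mcc - me)); mc1 <- min(W, ceiling(mcc + me))
      mnr_f <- mr1 - mr0 + 1L; mnc_f <- mc1 - mc0 + 1L
      mrs <- mr0 - 0.5 + (seq_len(mnr_f * S) - 0.5) / S
      mcs <- mc0 - 0.5 + (seq_len(mnc_f * S) - 0.5) / S
      mdy <- matrix(mrs - mcr, mnr_f * S, mnc_f * S)
      mdx <- matrix(mcs - mcc, mnr_f * S, mnc_f * S, byrow = TRUE)
      mdisk <- mdx^2 + mdy^2 <= mnr^2
      mcov <- box_downsample(mdisk + 0, S)
      dna[mr0:mr1, mc0:mc1] <- dna[mr0:mr1, mc0:mc1] +
        spec$mn_dna_frac * spec$dna_level * mcov
      add_obj(data.frame(kind = "micronucleus", id = NA_integer_,
                         nucleus_id = i, center_row = mcr, center_col = mcc,
                         radius = mnr, aspect = NA_real_,
                         orientation = mn_theta, lobe_amp_total = NA_real_,
                         analytic_eccentricity = NA_real_,
                         analytic_area = pi * mnr^2,
                         dna_frac = spec$mn_dna_frac))
      wm <- which(mcov >= 0.5, arr.ind = TRUE)
      masks[[length(masks) + 1L]] <- (mc0 - 1L + wm[, 2] - 1L) * H +
        (mr0 - 1L + wm[, 1])
    }
  }
  truth <- do.call(rbind, truth)
  truth$id <- seq_len(nrow(truth))
  truth$area_px <- vapply(masks, length, numeric(1))
  noisify <- function(m) {
    m <- m + spec$background
    if (spec$poisson) m <- matrix(stats::rpois(length(m), pmax(m, 0)),
                                  nrow(m), ncol(m))
    if (spec$noise_sd > 0) m <- m + stats::rnorm(length(m), 0, spec$noise_sd)
    pmax(m, 0)
  }
  channels <- list(
    dna = channel_image(noisify(dna), "dna"),
    laminB = channel_image(noisify(lamb), "laminB"),
    laminAC = channel_image(noisify(lac), "laminAC"))
  list(channels = channels, truth = truth, masks = masks)
}

#' Score detections against planted ground truth
#'
#' Greedy one-to-one matching by descending intersection-over-union;
#' matched pairs with IoU at least `iou_min` are true positives.
#'
#' @param truth_masks list of pixel-index vectors for the planted objects.
#' @param det_masks list of pixel-index vectors for the detections.
#' @param iou_min matching threshold in (0, 1], default 0.3.
#' @return list with `sensitivity`, `fdr`, `tp`, `fp`, `fn`, and the
#'   index pairs of matches (`matches`, two-column matrix truth/detection).
#' @export
score_detections <- function(truth_masks, det_masks, iou_min = 0.3) {
  stopifnot(iou_min > 0, iou_min <= 1)
  nt <- length(truth_masks); nd <- length(det_masks)
  if (nd == 0L || nt == 0L) {
    return(list(sensitivity = if (nt == 0L) NA_real_ else 0,
                fdr = if (nd == 0L) NA_real_ else 1,
                tp = 0L, fp = nd, fn = nt,
                matches = matrix(integer(0), 0, 2,
                                 dimnames = list(NULL, c("truth", "det")))))
  }
  iou <- matrix(0, nt, nd)
  for (i in seq_len(nt)) for (j in seq_len(nd))
    iou[i, j] <- iou_sets(truth_masks[[i]], det_masks[[j]])
  matches <- matrix(integer(0), 0, 2,
                    dimnames = list(NULL, c("truth", "det")))
  used_t <- logical(nt); used_d <- logical(nd)
  repeat {
    iou[used_t, ] <- -1; iou[, used_d] <- -1
    m <- which.max(iou)
    if (iou[m] < iou_min) break
    i <- (m - 1L) %% nt + 1L; j <- (m - 1L) %/% nt + 1L
    matches <- rbind(matches, c(i, j))
    used_t[i] <- TRUE; used_d[j] <- TRUE
    if (all(used_t) || all(used_d)) break
  }
  tp <- nrow(matches)
  list(sensitivity = tp / nt, fdr = (nd - tp) / nd,
       tp = tp, fp = nd - tp, fn = nt - tp, matches = matches)
}

#' Match segmented nucleus labels to planted nuclei
#'
#' Utility for planted-recovery evaluations: each planted nucleus is mapped
#' to the segmentation label at its centre (0 when unsegmented).
#'
#' @param truth ground-truth data.frame from [render_scene()].
#' @param labels integer label mask.
#' @return named integer vector, names = truth `nucleus_id`.
#' @export
match_nuclei <- function(truth, labels) {
  nuc <- truth[truth$kind == "nucleus", ]
  out <- vapply(seq_len(nrow(nuc)), function(i)
    as.integer(labels[round(nuc$center_row[i]), round(nuc$center_col[i])]),
    integer(1))
  names(out) <- nuc$nucleus_id
  out
}
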