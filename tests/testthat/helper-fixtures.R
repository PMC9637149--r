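# Shared fixtures: small, fast synthetic specs and brute-force oracles.

# A small hypha in a 256 px frame (25.6 um field of view): fast to generate,
# big enough for segmentation and correlation to behave like the full-size
# default.
small_spec <- function(seed = 1L, n_droplets = 5L, noise = "none", ...) {
  args <- utils::modifyList(
    list(image_size_pix = 256L, hypha_length_um = 20, hypha_width_um = 6,
         n_droplets = n_droplets, noise = noise, seed = seed),
    list(...))
  do.call(synthetic_spec, args)
}

# A mid-size hypha in a 512 px frame, used where correlation statistics need
# more droplets than the 256 px frame can host.
mid_spec <- function(seed = 1L, n_droplets = 10L, noise = "gaussian", ...) {
  args <- utils::modifyList(
    list(image_size_pix = 512L, hypha_length_um = 40, hypha_width_um = 8,
         n_droplets = n_droplets, noise = noise, seed = seed),
    list(...))
  do.call(synthetic_spec, args)
}

# Brute-force normalized fluctuation autocorrelation with periodic lags:
# the O(N^4) oracle for autocorrelate().
brute_autocorr <- function(m) {
  n_r <- nrow(m); n_c <- ncol(m)
  mu <- mean(m)
  dm <- m - mu
  g <- matrix(0, n_r, n_c)
  for (dx in 0:(n_c - 1)) for (dy in 0:(n_r - 1)) {
    shifted <- dm[((seq_len(n_r) - 1 + dy) %% n_r) + 1,
                  ((seq_len(n_c) - 1 + dx) %% n_c) + 1]
    g[dy + 1, dx + 1] <- mean(dm * shifted) / mu^2
  }
  # arrange zero lag at centre like autocorrelate()
  s1 <- floor(n_r / 2); s2 <- floor(n_c / 2)
  g[c((s1 + 1):n_r, 1:s1), c((s2 + 1):n_c, 1:s2)]
}

# Recursive flood-fill 8-connected labelling: the oracle for
# analyze_particles() component structure. Returns sorted component sizes.
brute_component_sizes <- function(mask) {
  n_r <- nrow(mask); n_c <- ncol(mask)
  seen <- matrix(FALSE, n_r, n_c)
  sizes <- integer(0)
  for (i in seq_len(n_r)) for (j in seq_len(n_c)) {
    if (!mask[i, j] || seen[i, j]) next
    size <- 0L
    stack <- list(c(i, j))
    seen[i, j] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (di in -1:1) for (dj in -1:1) {
        r <- p[1] + di; c <- p[2] + dj
        if (r >= 1 && r <= n_r && c >= 1 && c <= n_c &&
            mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sort(sizes)
}

# Pairwise centre distances (um) of a ground truth, to check droplet
# separation preconditions.
min_center_gap_um <- function(gt, pixel_size_um) {
  ctr <- gt$droplet_centers * pixel_size_um
  if (nrow(ctr) < 2) return(Inf)
  min(dist(ctr))
}

# Generate one full-size hypha in a given regime and quantify it by both
# methods; returns recovery ratios against the generator's ground truth.
quantify_regime_image <- function(density_per_um2, diameter_um, seed,
                                  pixel_size_um = 0.1,
                                  hypha_length_um = 80, hypha_width_um = 10) {
  n <- max(1L, round(density_per_um2 *
                       capsule_area(hypha_length_um, hypha_width_um)))
  spec <- synthetic_spec(seed = seed, n_droplets = n,
                         diameter_mean_um = diameter_um,
                         pixel_size_um = pixel_size_um,
                         hypha_length_um = hypha_length_um,
                         hypha_width_um = hypha_width_um)
  sim <- generate_hypha_image(spec)
  gt <- sim$ground_truth
  mask <- estimate_hypha_mask(sim$image)
  ics <- tryCatch(ics_quantify(sim$image, mask = mask),
                  error = function(e) NULL)
  psa <- psa_quantify(sim$image, mask = mask)
  data.frame(
    seed = seed, true_n = nrow(gt$droplet_centers),
    true_density = gt$true_density_per_um2,
    ics_n = if (is.null(ics)) NA_real_ else ics$n_ld,
    psa_n = psa$n_ld,
    ics_density_ratio = if (is.null(ics)) NA_real_ else
      ics$density_per_um2 / gt$true_density_per_um2,
    psa_density_ratio = psa$density_per_um2 / gt$true_density_per_um2,
    ics_diameter = if (is.null(ics)) NA_real_ else ics$mean_diameter_um,
    psa_diameter = psa$mean_diameter_um
  )
}
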