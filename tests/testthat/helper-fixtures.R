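# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except files the tests themselves write to tempdir().

# Straight synthetic ridge at a chosen orientation; centerline offsets are
# half-integer so an even-width top-hat rasterizes to exactly `diameter_um`
# full-coverage pixels at 1 um/px.
ridge_fixture <- function(orientation = c("horizontal", "vertical", "diagonal"),
                          diameter_um = 20, noise_sd = 0, n_frames = 1,
                          H = 64, W = 64, diameter_fun = NULL, seed = 1) {
  orientation <- match.arg(orientation)
  cy <- H / 2 - 0.5; cx <- W / 2 - 0.5  # pixel-boundary centering
  centerline <- switch(orientation,
    horizontal = rbind(c(cy, 4), c(cy, W - 5)),
    vertical   = rbind(c(4, cx), c(H - 5, cx)),
    diagonal   = rbind(c(5, 5), c(H - 6, W - 6)))
  spec <- vessel_spec(centerline,
                      diameter_um = if (is.null(diameter_fun)) diameter_um else diameter_fun,
                      contrast = 0.6, noise_sd = noise_sd, background = 0.2)
  make_vessel_stack(spec, list(H = H, W = W, pixel_size_um = 1,
                               n_frames = n_frames, frame_interval_s = 2),
                    seed = seed)
}

# interior measurement point (0-based) for each ridge orientation
ridge_point <- function(orientation) {
  switch(orientation, horizontal = c(31.5, 30), vertical = c(30, 31.5),
         diagonal = c(30, 30))
}

rect_mask <- function(H, W, rows, cols) {
  m <- matrix(FALSE, H, W)
  m[rows, cols] <- TRUE
  m
}

# two-ROI angiography fixture with programmed arterial/venous boli
angio_fixture <- function(arterial = bolus_spec(1, 1.5, 110, baseline_iu = 10),
                          venous = bolus_spec(2.5, 1.5, 80, baseline_iu = 10),
                          duration_s = 12, noise_sd = 0, seed = 1,
                          shape = "linear") {
  H <- 32; W <- 32
  ra <- roi("artery", mask = rect_mask(H, W, 5:10, 5:10))
  rv <- roi("vein", mask = rect_mask(H, W, 20:25, 20:25))
  make_angio_stack(list(A = list(roi = ra, spec = arterial),
                        V = list(roi = rv, spec = venous)),
                   list(H = H, W = W, pixel_size_um = 2, fs = 30,
                        duration_s = duration_s),
                   seed = seed, noise_sd = noise_sd, shape = shape)
}

# full-enumeration two-sided Mann-Whitney p for tie-free samples: the exact
# permutation distribution of U over all C(n+m, n) group assignments
mw_enum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  vals <- c(x, y)
  combs <- utils::combn(n + m, n)
  r_all <- rank(vals)
  u_obs <- sum(r_all[seq_len(n)]) - n * (n + 1) / 2
  us <- apply(combs, 2, function(idx) {
    sum(rank(vals)[idx]) - n * (n + 1) / 2
  })
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(p, 1)
}

small_pipeline_config <- function(seed = 11) {
  cfg <- demo_config(seed)
  for (i in seq_along(cfg$groups)) cfg$groups[[i]]$n_animals <- 2
  cfg$ecog_params$duration_s <- 120
  cfg$ecog_params$day1_duration_s <- 60
  for (i in seq_along(cfg$groups)) {
    cfg$groups[[i]]$n_events <- min(cfg$groups[[i]]$n_events, 3)
  }
  cfg
}
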