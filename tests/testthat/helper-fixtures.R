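# Shared small fixtures, built in code. Heavier objects are memoized within a
# test run so several test files can reuse them.

.fixture_env <- new.env(parent = emptyenv())

memo_fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

small_geom <- function() encoder_geometry(32, 32, 11)

small_mosaic <- function() {
  memo_fixture("small_mosaic", function() {
    build_mosaic(c(352, 352),
                 spacings_um = c(ON_parasol = 150, OFF_parasol = 150,
                                 ON_midget = 75, OFF_midget = 75),
                 jitter_fraction = 0.08, seed = 3)
  })
}

small_encoder <- function() {
  memo_fixture("small_encoder", function() {
    sample_ground_truth_params(small_mosaic(), small_geom(), seed = 4)
  })
}

small_mask <- function() {
  memo_fixture("small_mask", function() valid_region(small_mosaic(), small_geom()))
}

texture_corpus <- function(n = 200, size = 32) {
  memo_fixture(sprintf("corpus_%d_%d", n, size), function() {
    lapply(seq_len(n), function(i) generate_texture_image(5000 + i, size, size))
  })
}

wiener_denoiser <- function() {
  memo_fixture("wiener_denoiser", function() {
    train_stand_in_denoiser(texture_corpus())
  })
}

# tiny three-cell encoder with short kernels for brute-force oracle tests
tiny_encoder <- function() {
  memo_fixture("tiny_encoder", function() {
    set.seed(42)
    geom <- encoder_geometry(16, 16, 11)
    bs <- list(temporal = raised_cosine_basis(4, 1, 40, log_stretch = 5),
               feedback = raised_cosine_basis(3, 1, 20, log_stretch = 5),
               coupling = raised_cosine_basis(2, 1, 10, log_stretch = 5),
               spatial_n = 4)
    # parameter scales kept small so |g| stays below ~12: double precision
    # can then represent 1 - sigmoid(g) accurately enough for the log-pmf
    # oracle to be meaningful at 1e-10
    mk_cell <- function(id, others) {
      crop <- list(rows = 4:12, cols = 4:12)
      lnbrc_cell(id, "ON_midget", crop$rows, crop$cols,
                 spatial = matrix(rnorm(81, sd = 0.25), 9, 9),
                 temporal_weights = rnorm(4, sd = 0.3),
                 feedback_weights = rnorm(3, sd = 0.4),
                 coupling_weights = matrix(rnorm(2 * length(others), sd = 0.2),
                                           2),
                 neighbors = others, bias = -3, basis_set = bs)
    }
    cells <- list(mk_cell(1, c(2, 3)), mk_cell(2, c(1, 3)), mk_cell(3, c(1, 2)))
    structure(list(cells = cells, mosaic = NULL,
                   geometry = geom, basis_set = bs),
              class = "rgc_encoder")
  })
}

random_tiny_movie <- function(seed, n_frames = 24) {
  set.seed(seed)
  frames <- array(runif(16 * 16 * n_frames), c(16, 16, n_frames))
  stim_movie(frames, 25 / 3, 11)
}

random_tiny_spikes <- function(seed, n_cells = 3, T = 200) {
  set.seed(seed)
  spike_trains(matrix(rbinom(n_cells * T, 1, 0.05), n_cells, T))
}
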