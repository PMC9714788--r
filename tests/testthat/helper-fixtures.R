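# Shared fixtures, built in code. The small phantom exercises every stage
# quickly; heavier reference-scenario objects are created lazily and cached
# for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

small_phantom_spec <- function(seed = 101) {
  phantom_spec(nrow = 32, ncol = 32, outer_radius = 14, ring_width = 3,
               seam_width = 2, n_per_group = 2, n_peaks = 60,
               n_up = 6, n_down = 5, n_clusters = 6, seed = seed)
}

small_truth <- function() {
  cached("small_truth", {
    generate_intensity_cubes(small_phantom_spec(), load_metabolite_db())
  })
}

small_dataset_dir <- function() {
  cached("small_dataset_dir", {
    dir <- file.path(tempdir(), "osteomsi_small_phantom")
    generate_dataset(small_phantom_spec(), load_metabolite_db(), dir)
    dir
  })
}

small_manifest <- function() {
  cached("small_manifest", {
    generate_dataset(small_phantom_spec(), load_metabolite_db(),
                     small_dataset_dir())
  })
}

# A tiny 2x2 processed-mode dataset for IO round-trips.
tiny_processed <- function() {
  msi_dataset(
    coords = data.frame(x = c(0L, 1L, 0L, 1L), y = c(0L, 0L, 1L, 1L)),
    mz = list(c(100, 200, 300), c(150, 250), c(100.5, 200.5, 300.5, 400.5),
              c(120, 220)),
    intensity = list(c(1, 2, 3), c(4, 5), c(6, 7, 8, 9), c(10, 11)),
    mode = "processed")
}

tiny_continuous <- function(seed = 42) {
  set.seed(seed)
  msi_dataset(
    coords = data.frame(x = rep(0:2, 3), y = rep(0:2, each = 3)),
    mz = sort(runif(20, 100, 1000)),
    intensity = matrix(runif(180), nrow = 9),
    mode = "continuous")
}

# Three annotated peaks on one grid: peaks 1-2 share a pathway and are
# strongly spatially correlated; peak 3 shares no pathway.
make_toy_net_inputs <- function() {
  set.seed(12)
  n_px <- 60
  img <- cbind(a = rnorm(n_px, 10), b = 0, c = rnorm(n_px, 10))
  img[, "b"] <- img[, "a"] * 2 + rnorm(n_px, 0, 0.01)
  cube <- structure(list(intensity = img,
                         coords = data.frame(x = rep(0:9, 6),
                                             y = rep(0:5, each = 10)),
                         peak_mz = c(100, 200, 300)),
                    class = "msi_datacube")
  mask <- roi_mask(matrix(2L, 6, 10))
  annos <- data.frame(peak_mz = c(100, 200, 300),
                      id = c("m1", "m2", "m3"), name = c("m1", "m2", "m3"),
                      adduct = "M-H", theo_mz = c(100, 200, 300), ppm = 0,
                      class = "X", endogenous = TRUE,
                      pathways = c("p1", "p1", "p2"), source = "metabolite")
  st <- data.frame(peak_mz = c(100, 200, 300), log2fc = c(2, -0.2, 0.4))
  list(cube = cube, mask = mask, annos = annos, st = st)
}
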