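# Shared fixtures, built once per test run.

# Tiny hand-built cell matrix: 4 genes x 6 cells, two groups, two patients
# per group. Counts chosen so positivity and compositions are easy to read.
tiny_cells <- function() {
  counts <- rbind(
    GENEA = c(0, 2, 0, 5, 0, 1),
    GENEB = c(1, 1, 1, 1, 1, 1),
    GENEC = c(0, 0, 0, 0, 0, 0),
    GENED = c(3, 0, 0, 0, 4, 0))
  colnames(counts) <- paste0("c", 1:6)
  meta <- data.frame(
    cell_id = colnames(counts),
    group = c("A", "A", "A", "B", "B", "B"),
    patient = c("A_P1", "A_P1", "A_P2", "B_P1", "B_P1", "B_P2"),
    cell_type = c("T cells", "Stromal", "T cells", "Stromal", "Stromal",
                  "Macrophages"),
    n_genes_detected = c(1500L, 2000L, 1000L, 900L, 2500L, 600L),
    n_umi = c(4000L, 5000L, 2500L, 2000L, 9000L, 1200L),
    mito_fraction = c(0.05, 0.10, 0.02, 0.20, 0.01, 0.08))
  cell_matrix(counts, meta)
}

# One moderate-scale default-structure simulation shared across tests.
.fixture_env <- new.env(parent = emptyenv())

sim_fixture <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- sim_config(cells_per_patient = 250, n_genes = 800, seed = 42L)
    .fixture_env$sim <- simulate_cells(cfg)
    .fixture_env$cfg <- cfg
  }
  .fixture_env$sim
}

seg_fixture <- function() {
  if (is.null(.fixture_env$seg)) {
    cfg <- sim_config(n_genes = 800, seed = 42L)
    .fixture_env$seg <- simulate_segments(cfg)
  }
  .fixture_env$seg
}

# random non-negative count matrix for oracle checks
random_counts <- function(nr, nc, lambda = 5) {
  m <- matrix(rpois(nr * nc, lambda), nr, nc,
              dimnames = list(sprintf("g%03d", seq_len(nr)),
                              sprintf("u%03d", seq_len(nc))))
  m
}
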