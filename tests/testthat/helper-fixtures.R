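# Shared fixtures built in code. Expensive objects are memoised per
# test run so several test files can reuse one construction.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

base_geometry <- function() {
  fixture("base_geometry", function()
    build_idealized(geometry_params(SR = 70, cap_thk = 65, core_thk = 500)))
}

base_plaque_materials <- function(E_core = 5, E_plaque = 600) {
  c(list(core = neo_hookean(E_core), plaque = neo_hookean(E_plaque)),
    table2_materials())
}

# single-layer neo-Hookean ring used by the mechanics oracle checks
oracle_ring_layers <- function() {
  data.frame(r_in = 1.8, r_out = 2.8, C10 = 100, region = "wall")
}

# Small synthetic feature/target table with the campaign schema. The
# strain features are smooth deterministic functions of the moduli,
# cap thickness and stenosis ratio (plus a little noise), so models
# trained on it have something real to learn.
toy_dataset <- function(n = 60, seed = 42, noise = 0.01) {
  set.seed(seed)
  tbl <- tibble::tibble(
    case_id = sprintf("T%04d", 1:n),
    geometry_id = rep_len(1:5, n),
    E_core = exp(runif(n, 0, log(100))),
    E_plaque = runif(n, 390, 1200),
    SR = runif(n, 40, 80),
    cap_thk = runif(n, 65, 300),
    core_thk = runif(n, 300, 800),
    status = "ok"
  )
  jitter <- function() exp(rnorm(n, sd = noise))
  base <- (795 / tbl$E_plaque)^0.9 * (60 / tbl$SR)^0.5
  tbl$eps_theta <- 0.004 * base * (140 / tbl$cap_thk)^0.05 * jitter()
  tbl$eps_cap <- -0.005 * base * (140 / tbl$cap_thk)^0.2 *
    (20 / tbl$E_core)^0.05 * jitter()
  tbl$eps_core <- -0.0045 * base * (20 / tbl$E_core)^0.15 * jitter()
  tbl$eps1 <- 1.3 * tbl$eps_theta
  tbl$eps2 <- -1.3 * tbl$eps_theta
  tbl$eps_core_sq <- tbl$eps_core^2
  tbl$eps_cap_sq <- tbl$eps_cap^2
  tbl$eps_theta_sq <- tbl$eps_theta^2
  atheromech:::as_dataset_table(tbl, provenance = list(backend = "toy", seed = seed))
}
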