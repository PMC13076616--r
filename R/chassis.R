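# Chassis: the fixed (non-evolvable) part of a circuit instance — arena,
# stimulus protocol, presynaptic positions and grouping, morphology and
# synapse placement. A genome plus a chassis fully specifies a model.

#' Build a circuit chassis
#'
#' Constructs the fixed scaffold a genome is evaluated on: presynaptic cell
#' positions grouped along the preferred axis (direction 0), the postsynaptic
#' back-end, and the stimulus protocol. The chassis is deterministic given
#' its seed; the genetic algorithm never changes it.
#'
#' @param backend `"minimal"` (two-cell linear detector), `"point"` (linear
#'   sum over an arbitrary population), or `"compartmental"` (passive cable
#'   model on a morphology, optionally with a spiking soma).
#' @param n_exc,n_inh Number of excitatory / inhibitory presynaptic cells.
#' @param n_groups Input groups along the preferred axis (quartiles of
#'   position by default).
#' @param arena An [arena()].
#' @param speeds Stimulus speeds (mm/s).
#' @param directions Motion directions (radians); direction 0 is the
#'   designated preferred direction.
#' @param placement `"retina"` (receptive fields in a circle over the soma,
#'   nearest-dendrite wiring) or `"cortex"` (wider coverage, random wiring,
#'   spiking presynaptic transmission).
#' @param placement_radius Radius of the input coverage circle (um).
#' @param morph Optional `emd_morphology`; otherwise generated.
#' @param morph_segments,morph_radius Surrogate morphology size.
#' @param g_unit Synaptic conductance per unit of presynaptic drive (nS).
#' @param e_inh Inhibitory reversal potential (mV).
#' @param dt_v Voltage solver step (ms).
#' @param adaptation Simulate readily-releasable-pool adaptation.
#' @param surround,inh_surround Include surround components for the
#'   excitatory / inhibitory populations.
#' @param plasticity Apply short-term plasticity parameters from the genome.
#' @param soma_spiking Add Na/K channels at the soma and count spikes.
#' @param protocol `"bar"` or `"grating"`.
#' @param periods Grating spatial periods (um/cycle) for the grating
#'   protocol.
#' @param separation Cell separation for the minimal backend (um).
#' @param seed Integer seed for placement and morphology.
#' @return An `emd_chassis`.
#' @export
build_chassis <- function(backend = c("compartmental", "point", "minimal"),
                          n_exc = 100, n_inh = 0, n_groups = 4,
                          arena = emdevolve::arena(),
                          speeds = c(0.25, 0.5, 1, 2, 4),
                          directions = 2 * pi * (0:11) / 12,
                          placement = c("retina", "cortex"),
                          placement_radius = 150, morph = NULL,
                          morph_segments = 352, morph_radius = 150,
                          g_unit = 0.75, e_inh = -70, dt_v = 0.1,
                          adaptation = TRUE, surround = FALSE,
                          inh_surround = FALSE, plasticity = FALSE,
                          soma_spiking = FALSE,
                          protocol = c("bar", "grating"),
                          periods = c(100, 200, 400, 800, 1600),
                          separation = 100, seed = NULL) {
  backend <- match.arg(backend)
  placement <- match.arg(placement)
  protocol <- match.arg(protocol)
  ch <- with_seed(seed, {
    if (backend == "minimal") {
      n_groups <- 2L
      cells <- tibble(cell = 1:2, pop = "exc",
                      x = c(-separation / 2, separation / 2), y = 0,
                      group = 1:2, polarity = "excitatory")
    } else {
      r_cov <- if (placement == "cortex") placement_radius * 4 / 3 else placement_radius
      cells <- bind_rows(
        random_population(n_exc, r_cov, "excitatory"),
        if (n_inh > 0) random_population(n_inh, r_cov, "inhibitory"))
      cells$cell <- seq_len(nrow(cells))
      cells <- assign_groups(cells, n_groups)
      cells$pop <- ifelse(cells$polarity == "inhibitory", "inh", "exc")
    }
    morph_out <- NULL; sites <- NULL
    if (backend == "compartmental") {
      morph_out <- morph %||% generate_dsgc_morphology(
        morph_segments, morph_radius, seed = derive_seed(seed %||% 0, "morph"))
      sites <- place_synapses(cells, morph_out, mode = placement,
                              seed = derive_seed(seed %||% 0, "sites"),
                              e_inh = e_inh)
    }
    list(cells = cells, morph = morph_out, sites = sites)
  })
  out <- structure(list(
    backend = backend, arena = arena, speeds = speeds,
    directions = directions, n_groups = n_groups, cells = ch$cells,
    morph = ch$morph, sites = ch$sites, placement = placement,
    cortical = placement == "cortex", g_unit = g_unit, e_inh = e_inh,
    dt_v = dt_v, adaptation = adaptation, surround = surround,
    inh_surround = inh_surround, plasticity = plasticity,
    soma_spiking = soma_spiking, protocol = protocol, periods = periods,
    seed = seed), class = "emd_chassis")
  if (backend == "compartmental") out <- precompute_cable(out)
  out
}

random_population <- function(n, radius, polarity) {
  if (n == 0) return(NULL)
  r <- radius * sqrt(runif(n))
  a <- runif(n, 0, 2 * pi)
  tibble(cell = seq_len(n), pop = "exc", x = r * cos(a), y = r * sin(a),
         group = NA_integer_, polarity = polarity)
}

# groups are position quantiles along the preferred (x) axis, assigned
# within each polarity so excitation and inhibition each span 1..n_groups
assign_groups <- function(cells, n_groups) {
  for (pol in unique(cells$polarity)) {
    i <- which(cells$polarity == pol)
    rk <- rank(cells$x[i], ties.method = "first")
    cells$group[i] <- as.integer(ceiling(rk / (length(i) / n_groups)))
  }
  cells$group <- pmin(cells$group, n_groups)
  cells
}

# static cable geometry so per-genome passives only rescale vectors
precompute_cable <- function(ch) {
  s <- ch$morph$segments
  parent_idx <- match(s$parent, s$id)
  ch$cable <- list(
    parent0 = as.integer(ifelse(s$parent == 0L, -1L, parent_idx - 1L)),
    area_cm2 = pi * s$diam * s$length * 1e-8,
    half_geom = (s$length / 2 * 1e-4) / (pi * (s$diam / 2 * 1e-4)^2),
    parent_idx = parent_idx,
    soma_idx = which(s$is_soma)[1])
  ch$cable$soma_area_um2 <- pi * s$diam[ch$cable$soma_idx] *
    s$length[ch$cable$soma_idx]
  ch
}

#' @export
print.emd_chassis <- function(x, ...) {
  cat(sprintf(
    "<emd_chassis:%s> %d exc / %d inh cells, %d groups, %d speeds x %d directions\n",
    x$backend, sum(x$cells$polarity == "excitatory"),
    sum(x$cells$polarity == "inhibitory"), x$n_groups, length(x$speeds),
    length(x$directions)))
  invisible(x)
}
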