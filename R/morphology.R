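#' Surrogate direction-selective ganglion cell morphology
#'
#' Procedurally grows a planar, radially branching dendritic arbor around a
#' somatic root: primary dendrites leave the soma at spread angles and extend
#' outward in fixed-length segments, branching stochastically until the
#' target segment count is reached. This is a synthetic surrogate with the
#' gross statistics of a ganglion-cell arbor (planar, radially symmetric,
#' ~300 um field), not a reconstruction.
#'
#' @param n_segments Total segments including the soma (default 352).
#' @param radius Maximal dendritic reach from the soma (um).
#' @param seed Integer seed; the arbor is deterministic given the seed.
#' @param n_primary Number of primary dendrites.
#' @param branch_prob Probability a growth step branches.
#' @return An `emd_morphology`: a tibble of segments with columns `id`,
#'   `parent` (0 for the root), `x`, `y`, `z`, `length`, `diam`, `is_soma`,
#'   ordered so every parent precedes its children.
#' @export
#' @examples
#' m <- generate_dsgc_morphology(60, seed = 1)
#' nrow(m$segments)
generate_dsgc_morphology <- function(n_segments = 352, radius = 150,
                                     seed = NULL, n_primary = 5,
                                     branch_prob = 0.35) {
  if (n_segments < 10) stop_invalid("n_segments must be >= 10")
  seg_len <- radius / 14
  with_seed(seed, grow_radial_arbor(n_segments, radius, seg_len, n_primary,
                                    branch_prob, planar = TRUE))
}

#' Surrogate cortical pyramidal-cell morphology
#'
#' A small apical/basal arbor: an apical trunk climbing from the soma with
#' oblique branches and a basal skirt of short dendrites. Synthetic surrogate
#' (see [generate_dsgc_morphology()]).
#'
#' @inheritParams generate_dsgc_morphology
#' @return An `emd_morphology`.
#' @export
generate_pyramidal_morphology <- function(n_segments = 69, radius = 200,
                                          seed = NULL) {
  if (n_segments < 10) stop_invalid("n_segments must be >= 10")
  with_seed(seed, {
    n_apical <- round(n_segments * 0.55)
    n_basal <- n_segments - 1L - n_apical
    segs <- init_soma(diam = 15)
    # apical trunk + obliques
    segs <- grow_from(segs, root = 1L, n_new = n_apical,
                      base_angle = pi / 2, angle_jitter = 0.25,
                      seg_len = radius / 12, branch_prob = 0.4,
                      max_r = radius)
    segs <- grow_from(segs, root = 1L, n_new = n_segments - nrow(segs) - n_basal,
                      base_angle = pi / 2, angle_jitter = 0.8,
                      seg_len = radius / 15, branch_prob = 0.5,
                      max_r = radius)
    while (nrow(segs) < n_segments) { # basal skirt, topped up to the target
      segs <- grow_from(segs, root = 1L, n_new = n_segments - nrow(segs),
                        base_angle = runif(1, -pi, 0), angle_jitter = 1.2,
                        seg_len = radius / 18, branch_prob = 0.4,
                        max_r = radius * 0.5)
    }
    new_morphology(segs)
  })
}

init_soma <- function(diam = 12) {
  tibble(id = 1L, parent = 0L, x = 0, y = 0, z = 0,
         length = diam, diam = diam, is_soma = TRUE,
         angle = 0)
}

new_morphology <- function(segs) {
  segs$angle <- NULL
  structure(list(segments = segs), class = "emd_morphology")
}

grow_radial_arbor <- function(n_segments, radius, seg_len, n_primary,
                              branch_prob, planar = TRUE) {
  segs <- init_soma()
  angles <- 2 * pi * (seq_len(n_primary) - 1) / n_primary +
    runif(1, 0, 2 * pi / n_primary)
  per <- ceiling((n_segments - 1L) / n_primary)
  left <- n_segments - 1L
  for (a in angles) {
    take <- min(per, left)
    if (take <= 0) break
    segs <- grow_from(segs, root = 1L, n_new = take, base_angle = a,
                      angle_jitter = 0.15, seg_len = seg_len,
                      branch_prob = branch_prob, max_r = radius)
    left <- n_segments - nrow(segs)
  }
  while (left > 0) { # top up if branches terminated early
    segs <- grow_from(segs, root = 1L, n_new = left,
                      base_angle = runif(1, 0, 2 * pi), angle_jitter = 0.15,
                      seg_len = seg_len, branch_prob = branch_prob,
                      max_r = radius * 1.1)
    left <- n_segments - nrow(segs)
  }
  new_morphology(segs)
}

# depth-first stochastic growth of one subtree; tips past max_r stop growing
grow_from <- function(segs, root, n_new, base_angle, angle_jitter, seg_len,
                      branch_prob, max_r) {
  tips <- list(list(parent = root, angle = base_angle, depth = 1L))
  added <- 0L
  while (added < n_new && length(tips) > 0) {
    i <- if (length(tips) == 1L) 1L else sample.int(length(tips), 1L)
    tip <- tips[[i]]
    tips[[i]] <- NULL
    p <- segs[segs$id == tip$parent, ]
    ang <- tip$angle + runif(1, -angle_jitter, angle_jitter)
    nx <- p$x + seg_len * cos(ang)
    ny <- p$y + seg_len * sin(ang)
    if (sqrt(nx^2 + ny^2) > max_r) next
    id <- nrow(segs) + 1L
    segs <- bind_rows(segs, tibble(
      id = id, parent = tip$parent, x = nx, y = ny, z = 0,
      length = seg_len, diam = max(0.4, 1.6 * 0.93^tip$depth),
      is_soma = FALSE, angle = ang))
    added <- added + 1L
    if (runif(1) < branch_prob && tip$depth < 40L) {
      dth <- runif(1, 0.3, 0.7)
      tips <- c(tips, list(
        list(parent = id, angle = ang - dth, depth = tip$depth + 1L),
        list(parent = id, angle = ang + dth, depth = tip$depth + 1L)))
    } else {
      tips <- c(tips, list(list(parent = id, angle = ang,
                                depth = tip$depth + 1L)))
    }
  }
  segs
}

#' @export
print.emd_morphology <- function(x, ...) {
  s <- x$segments
  cat(sprintf("<emd_morphology> %d segments, reach %.0f um\n",
              nrow(s), max(sqrt(s$x^2 + s$y^2))))
  invisible(x)
}

#' Read / write SWC morphology files
#'
#' Standard 7-column SWC (id, type, x, y, z, radius, parent) in micrometres;
#' type 1 marks the soma, type 3 dendrite. Segment length is reconstructed
#' from the distance to the parent on read.
#'
#' @param morph An `emd_morphology`.
#' @param path File path.
#' @return `read_swc()` returns an `emd_morphology`; `write_swc()` its input,
#'   invisibly.
#' @export
write_swc <- function(morph, path) {
  s <- morph$segments
  df <- data.frame(id = s$id, type = ifelse(s$is_soma, 1L, 3L),
                   x = s$x, y = s$y, z = s$z, radius = s$diam / 2,
                   parent = ifelse(s$parent == 0L, -1L, s$parent))
  utils::write.table(df, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(morph)
}

#' @rdname write_swc
#' @export
read_swc <- function(path) {
  df <- utils::read.table(path, col.names = c("id", "type", "x", "y", "z",
                                              "radius", "parent"))
  df <- df[order(df$id), ]
  len <- numeric(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (df$parent[i] == -1L) {
      len[i] <- df$radius[i] * 2
    } else {
      p <- match(df$parent[i], df$id)
      len[i] <- sqrt((df$x[i] - df$x[p])^2 + (df$y[i] - df$y[p])^2 +
                       (df$z[i] - df$z[p])^2)
    }
  }
  new_morphology(tibble(
    id = as.integer(df$id), parent = as.integer(ifelse(df$parent == -1L, 0L, df$parent)),
    x = df$x, y = df$y, z = df$z, length = len, diam = df$radius * 2,
    is_soma = df$type == 1L))
}

#' Passive membrane properties
#'
#' @param g_pas Passive conductance density (S/cm^2).
#' @param c_m Specific capacitance (uF/cm^2).
#' @param e_rest Resting / leak reversal potential (mV).
#' @param r_a Axial resistivity (Ohm cm).
#' @return An `emd_passive` parameter set.
#' @export
passive_properties <- function(g_pas = 4e-4, c_m = 1, e_rest = -60,
                               r_a = 150) {
  check_positive(g_pas, "g_pas"); check_positive(c_m, "c_m")
  check_positive(r_a, "r_a")
  structure(list(g_pas = g_pas, c_m = c_m, e_rest = e_rest, r_a = r_a),
            class = "emd_passive")
}

#' Map presynaptic cells onto dendritic segments
#'
#' Retinal mode connects every cell to the dendritic segment nearest its
#' receptive-field center (retinotopic wiring); cortical mode assigns
#' uniformly random segments independent of receptive-field position.
#'
#' @param positions Tibble/data frame with one row per cell and columns `x`,
#'   `y` (receptive-field centers, um) and optionally `polarity`.
#' @param morph An `emd_morphology`.
#' @param mode `"retina"` or `"cortex"`.
#' @param seed Integer seed (cortical assignment is random).
#' @param e_exc,e_inh Synaptic reversal potentials (mV).
#' @return Tibble with one synapse per cell: `cell`, `segment`, `e_syn`.
#' @export
place_synapses <- function(positions, morph, mode = c("retina", "cortex"),
                           seed = NULL, e_exc = 0, e_inh = -70) {
  mode <- match.arg(mode)
  s <- morph$segments
  if (nrow(s) == 0) stop_invalid("empty morphology")
  n <- nrow(positions)
  if (n == 0) stop_invalid("empty presynaptic population")
  pol <- if ("polarity" %in% names(positions)) {
    positions[["polarity"]]
  } else rep("excitatory", n)
  seg <- if (mode == "retina") {
    vapply(seq_len(n), function(i) {
      d2 <- (s$x - positions$x[i])^2 + (s$y - positions$y[i])^2
      s$id[which.min(d2)]
    }, integer(1))
  } else {
    with_seed(seed, sample(s$id, n, replace = TRUE))
  }
  tibble(cell = seq_len(n), segment = as.integer(seg),
         e_syn = ifelse(pol == "inhibitory", e_inh, e_exc))
}
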