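# Serialization: spike records, weight-snapshot archives, YAML configuration
# and JSON run manifests. Formats are plain text, diffable and documented
# here; see the column schemas in each writer.

#' Write / read a spike record
#'
#' Two-column whitespace-delimited event format (`neuron` integer, `time` ms
#' with 6 decimal places), preceded by `#`-prefixed header lines carrying
#' `n_neurons` and `duration_ms`. Reading restores the record exactly and
#' sorts events canonically by (time, neuron); malformed lines fail with
#' their line number.
#'
#' @param spikes Data frame with `neuron`, `time`, or a `tacs_sim`.
#' @param path Output file.
#' @param n_neurons,duration_ms Header metadata (inferred from a `tacs_sim`).
#' @return `write_spikes`: the path, invisibly. `read_spikes`: a data frame
#'   with attributes `n_neurons` and `duration_ms`.
#' @export
write_spikes <- function(spikes, path, n_neurons = NULL, duration_ms = NULL) {
  if (inherits(spikes, "tacs_sim")) {
    n_neurons <- n_neurons %||% spikes$n_neurons
    duration_ms <- duration_ms %||% spikes$duration_ms
    spikes <- spikes$spikes
  }
  stopifnot(!is.null(n_neurons), !is.null(duration_ms))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# tacsnet spike record",
               sprintf("# n_neurons %d", as.integer(n_neurons)),
               sprintf("# duration_ms %.6f", duration_ms)), con)
  if (nrow(spikes) > 0)
    writeLines(sprintf("%d %.6f", spikes$neuron, spikes$time), con)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  get_hdr <- function(key) {
    m <- grep(paste0("^# ", key, " "), lines[hdr], value = TRUE)
    if (length(m) != 1) stop("missing header field: ", key)
    as.numeric(sub(paste0("^# ", key, " "), "", m))
  }
  n_neurons <- as.integer(get_hdr("n_neurons"))
  duration_ms <- get_hdr("duration_ms")
  body <- which(!hdr & nzchar(lines))
  neuron <- integer(length(body)); time <- numeric(length(body))
  for (k in seq_along(body)) {
    parts <- strsplit(trimws(lines[body[k]]), "[[:space:]]+")[[1]]
    if (length(parts) != 2 || anyNA(suppressWarnings(as.numeric(parts))))
      stop(sprintf("malformed spike line %d: '%s'", body[k], lines[body[k]]))
    neuron[k] <- as.integer(parts[1]); time[k] <- as.numeric(parts[2])
  }
  if (any(neuron < 1 | neuron > n_neurons))
    stop("neuron id outside 1..n_neurons")
  if (any(time < 0 | time > duration_ms))
    stop("spike time outside [0, duration_ms]")
  ord <- order(time, neuron)
  out <- data.frame(neuron = neuron[ord], time = time[ord])
  attr(out, "n_neurons") <- n_neurons
  attr(out, "duration_ms") <- duration_ms
  out
}

#' Write / read a weight-snapshot archive
#'
#' Tab-separated text archive holding the edge list and one full-precision
#' weight column per snapshot time: header lines (`#` prefixed) record the
#' snapshot times in seconds; the body columns are `pre`, `post`, then one
#' `g@<time>` column per snapshot. Reading is lossless.
#'
#' @param snapshots Matrix (synapses x times) of weights, or a `tacs_sim`.
#' @param network The `tacs_network` (for the edge list).
#' @param path Output file.
#' @param times Snapshot times, s.
#' @param synapse_idx Rows of `network$synapses` matching the matrix rows.
#' @return `write_weights`: the path, invisibly. `read_weights`: list with
#'   `times`, `edges` (data frame `pre`, `post`) and `snapshots` matrix.
#' @export
write_weights <- function(snapshots, network, path, times = NULL,
                          synapse_idx = NULL) {
  if (inherits(snapshots, "tacs_sim")) {
    times <- times %||% snapshots$snapshot_times
    synapse_idx <- synapse_idx %||% snapshots$snapshot_synapses
    snapshots <- snapshots$snapshots
  }
  stopifnot(is.matrix(snapshots), length(times) == ncol(snapshots))
  if (is.null(synapse_idx)) synapse_idx <- seq_len(nrow(snapshots))
  syn <- network$synapses[synapse_idx, , drop = FALSE]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# tacsnet weight archive",
               paste("# times_s", paste(sprintf("%.17g", times), collapse = " "))),
             con)
  writeLines(paste("pre", "post",
                   paste(sprintf("g@%g", times), collapse = "\t"), sep = "\t"),
             con)
  body <- cbind(syn$pre, syn$post,
                matrix(sprintf("%.17g", snapshots), nrow = nrow(snapshots)))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  tline <- grep("^# times_s ", lines, value = TRUE)
  if (length(tline) != 1) stop("missing times_s header")
  times <- as.numeric(strsplit(sub("^# times_s ", "", tline), " ")[[1]])
  body <- lines[!grepl("^#", lines)]
  header <- strsplit(body[1], "\t")[[1]]
  if (header[1] != "pre" || header[2] != "post") stop("malformed column header")
  rows <- strsplit(body[-1], "\t")
  mat <- do.call(rbind, lapply(rows, as.numeric))
  if (is.null(mat)) mat <- matrix(numeric(0), 0, length(times) + 2)
  list(times = times,
       edges = data.frame(pre = as.integer(mat[, 1]),
                          post = as.integer(mat[, 2])),
       snapshots = mat[, -(1:2), drop = FALSE])
}

#' Default experiment configuration
#'
#' The full parameter set of the study conditions: network composition,
#' synaptic and plasticity constants, noise, stimulation and schedule
#' defaults, as a nested list matching the YAML configuration schema of
#' [read_config()].
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    dt = 0.1,
    network = list(kind = "layer", n_neurons = 2000, p_connect = 0.1,
                   mtc = list(family = "gaussian", mean = 10, sd = 3, lower = 1),
                   g_0_EE = 5e-5, g_0_EI = 5e-5, g_0_IE = 25e-5, g_0_II = 25e-5,
                   delay_min = 0.5, delay_max = 1,
                   v_thr = -54, v_rest = -60, v_rest_jitter = 0.2,
                   tau_ref = 2),
    pair = list(tau_1 = 10, tau_2 = 14, g_0 = 0.1, delay = 0.5),
    stdp = list(A_plus = 0.02, A_minus = 0.01, gamma_plus = 10,
                gamma_minus = 10),
    noise = list(mu = 5.5, sigma = 1),
    stim = list(amplitude = 1, frequency = 25, phase = 0),
    schedule = list(t_pre_end = 4, t_stim_end = 40, t_total = 60),
    seed = 1)
}

#' Read and validate a YAML experiment configuration
#'
#' Missing keys take their defaults from [default_config()]; unknown keys are
#' rejected by name. An empty or absent file yields the full default
#' configuration.
#'
#' @param path YAML file path, or `NULL` for defaults.
#' @return Validated nested list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  stopifnot(file.exists(path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  check_keys <- function(user, ref, prefix = "") {
    unknown <- setdiff(names(user), names(ref))
    if (length(unknown) > 0)
      stop("unknown configuration key(s): ",
           paste0(prefix, unknown, collapse = ", "), call. = FALSE)
    for (nm in names(user))
      if (is.list(ref[[nm]]) && is.list(user[[nm]]))
        check_keys(user[[nm]], ref[[nm]], paste0(prefix, nm, "."))
  }
  check_keys(user, cfg)
  utils::modifyList(cfg, user)
}

#' Write a configuration to YAML
#'
#' @param config Nested list as from [read_config()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON record sufficient to reproduce a run: configuration snapshot, master
#' and child seeds, package version, wall-clock metadata and an inventory of
#' output files with MD5 checksums.
#'
#' @param path Output JSON file.
#' @param config Configuration list used for the run.
#' @param seed Master seed.
#' @param child_seeds Derived per-trial seeds.
#' @param files Character vector of output files to inventory.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, config, seed, child_seeds = integer(0),
                           files = character(0)) {
  manifest <- list(
    package = "tacsnet",
    version = as.character(utils::packageVersion("tacsnet")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    child_seeds = child_seeds,
    config = config,
    files = if (length(files) > 0)
      data.frame(path = files, md5 = unname(tools::md5sum(files)))
    else data.frame(path = character(0), md5 = character(0)))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
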