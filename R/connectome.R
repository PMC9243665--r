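#' Build a synthetic olivocerebellar connectome
#'
#' Statistical stand-in for a morphology-based reconstruction: for every
#' connection group each target cell draws its configured number of distinct
#' source cells uniformly without replacement, so the mean inbound degree
#' equals the configured convergence exactly. Every Purkinje cell receives
#' exactly one climbing-fiber (IO) source under the default configuration.
#' Fully deterministic given `(config, seed)`.
#'
#' @param config Network configuration, see [default_network_config()].
#' @param seed Integer seed for the connectome sampling stream.
#' @param neuron_params Per-population neuron parameters attached to the
#'   connectome (defaults to [default_neuron_params()]).
#' @return Object of class `connectome`: population table, named list of
#'   synapse groups (1-based `pre`/`post` local indices, per-edge `weight`,
#'   group `delay`, `sign`, `plastic`), the build seed and scale.
#' @export
build_connectome <- function(config = default_network_config(), seed = 1,
                             neuron_params = default_neuron_params()) {
  scale <- config$scale %||% 1
  stopifnot(scale > 0)
  scaled_pops <- c("mf", "GrC", "GoC", "MLI")
  sizes <- vapply(config$populations, function(p) as.numeric(p$size), 0)
  if (any(sizes < 1)) stop("population sizes must be >= 1")
  for (nm in intersect(names(sizes), scaled_pops))
    sizes[nm] <- max(1, round(sizes[nm] * scale))
  if (anyDuplicated(names(sizes))) stop("population names must be unique")

  built <- with_seed(seed, {
    ie_offsets <- lapply(stats::setNames(nm = setdiff(names(sizes), "mf")),
                         function(pop) {
      j <- neuron_params[[pop]]$I_e_jitter %||% 0
      runif(sizes[[pop]], -j, j)
    })
    groups <- lapply(config$connections, function(cc) {
      src <- cc$source; tgt <- cc$target
      if (!src %in% names(sizes) || !tgt %in% names(sizes))
        stop("unknown population in connection: ", src, "-", tgt)
      n_src <- sizes[[src]]; n_tgt <- sizes[[tgt]]
      k <- cc$convergence
      if (k < 0) stop("negative convergence for ", cc$source, "-", cc$target)
      # at reduced scale, cap convergences at the shrunken source size
      # (anatomical convergences stay put; mass convergences saturate)
      if (cc$source %in% scaled_pops && scale < 1) k <- min(k, n_src)
      if (k > n_src)
        stop("convergence ", k, " exceeds source population size ", n_src,
             " for group ", cc$source, "-", cc$target)
      if (k == 0) {
        pre <- integer(0); post <- integer(0)
      } else {
        pre <- as.integer(unlist(lapply(seq_len(n_tgt), function(j)
          sample.int(n_src, k, replace = FALSE))))
        post <- rep(seq_len(n_tgt), each = k)
      }
      list(source = src, target = tgt, pre = pre, post = post,
           weight = rep(as.numeric(cc$weight), length(pre)),
           ref_weight = as.numeric(cc$weight),
           delay = as.numeric(cc$delay), sign = as.integer(cc$sign),
           plastic = isTRUE(cc$plastic), convergence = k)
    })
    list(groups = groups, ie_offsets = ie_offsets)
  })

  structure(list(
    populations = data.frame(name = names(sizes), size = as.integer(sizes),
                             stringsAsFactors = FALSE),
    groups = built$groups,
    ie_offsets = built$ie_offsets,
    neuron_params = neuron_params,
    seed = as.integer(seed), scale = scale, config = config
  ), class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("olivocerebellar connectome (seed ", x$seed, ", scale ", x$scale, ")\n",
      sep = "")
  cat(" populations:",
      paste(sprintf("%s=%d", x$populations$name, x$populations$size),
            collapse = ", "), "\n")
  cnt <- vapply(x$groups, function(g) length(g$pre), 0L)
  cat(" groups:", paste(sprintf("%s(%d)", names(x$groups), cnt),
                        collapse = ", "), "\n")
  invisible(x)
}

pop_size <- function(connectome, name) {
  i <- match(name, connectome$populations$name)
  if (is.na(i)) stop("unknown population: ", name)
  connectome$populations$size[i]
}

#' Count synapses of a connection group
#'
#' @param connectome A `connectome`.
#' @param group Group label, e.g. `"pf-PC"`.
#' @return Integer edge count.
#' @export
count_synapses <- function(connectome, group) {
  if (!group %in% names(connectome$groups))
    stop("unknown synapse group: ", group)
  length(connectome$groups[[group]]$pre)
}

#' Structural excitation/inhibition ratio onto Purkinje cells
#'
#' Ratio between the number of excitatory (parallel fiber, ascending axon,
#' climbing fiber) and inhibitory (molecular-layer interneuron) synapses onto
#' the Purkinje population. Equals 62.3 under the default control
#' configuration by calibration of the per-target convergences.
#'
#' @param connectome A `connectome` containing the `pf-PC`, `aa-PC`, `IO-PC`
#'   and `MLI-PC` groups.
#' @return Dimensionless ratio.
#' @export
structural_ei_ratio <- function(connectome) {
  need <- c("pf-PC", "aa-PC", "IO-PC", "MLI-PC")
  miss <- setdiff(need, names(connectome$groups))
  if (length(miss)) stop("missing PC afferent groups: ",
                         paste(miss, collapse = ", "))
  exc <- count_synapses(connectome, "pf-PC") +
    count_synapses(connectome, "aa-PC") + count_synapses(connectome, "IO-PC")
  inh <- count_synapses(connectome, "MLI-PC")
  if (inh == 0) stop("degenerate E/I ratio: no inhibitory synapses onto PCs")
  exc / inh
}

#' Write a connectome archive
#'
#' Inspectable plain-text archive: `populations.json` (sizes, seed, scale,
#' group metadata) plus one CSV per synapse group with columns
#' `pre_id`, `post_id`, `weight`, `delay`.
#'
#' @param connectome A `connectome`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(connectome, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    populations = as.list(stats::setNames(connectome$populations$size,
                                          connectome$populations$name)),
    seed = connectome$seed, scale = connectome$scale,
    ie_offsets = connectome$ie_offsets,
    groups = lapply(connectome$groups, function(g)
      list(source = g$source, target = g$target, sign = g$sign,
           delay = g$delay, plastic = g$plastic,
           ref_weight = g$ref_weight %||% NA))
  )
  jsonlite::write_json(meta, file.path(path, "populations.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(connectome$groups)) {
    g <- connectome$groups[[nm]]
    df <- data.frame(pre_id = g$pre, post_id = g$post, weight = g$weight,
                     delay = rep(g$delay, length(g$pre)))
    write.csv(df, file.path(path, paste0(nm, ".csv")), row.names = FALSE)
  }
  invisible(path)
}

#' Read a connectome archive written by [write_connectome()]
#'
#' @param path Archive directory.
#' @param neuron_params Neuron parameters to attach (archive stores wiring
#'   only).
#' @return A `connectome`.
#' @export
read_connectome <- function(path, neuron_params = default_neuron_params()) {
  meta <- jsonlite::read_json(file.path(path, "populations.json"),
                              simplifyVector = TRUE)
  groups <- lapply(stats::setNames(names(meta$groups), names(meta$groups)),
                   function(nm) {
    gm <- meta$groups[[nm]]
    df <- read.csv(file.path(path, paste0(nm, ".csv")))
    list(source = gm$source, target = gm$target,
         pre = as.integer(df$pre_id), post = as.integer(df$post_id),
         weight = as.numeric(df$weight),
         ref_weight = if (is.null(gm$ref_weight) || is.na(gm$ref_weight))
           NULL else as.numeric(gm$ref_weight),
         delay = as.numeric(gm$delay),
         sign = as.integer(gm$sign), plastic = isTRUE(gm$plastic),
         convergence = NA)
  })
  structure(list(
    populations = data.frame(name = names(meta$populations),
                             size = as.integer(unlist(meta$populations)),
                             stringsAsFactors = FALSE),
    groups = groups, neuron_params = neuron_params,
    ie_offsets = lapply(meta$ie_offsets, as.numeric),
    seed = as.integer(meta$seed), scale = meta$scale, config = NULL
  ), class = "connectome")
}
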