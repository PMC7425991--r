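# Model JSON reader/writer with schema validation (lossless round trip),
# plus small CSV/JSON writers for ensembles and reports.

#' Write a model specification to JSON
#' @param net a `ReactionNetwork`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_model_json <- function(net, path) {
  doc <- list(
    schema = "sigmux-model/1",
    variant = net$variant,
    species = net$species,
    omega = net$omega,
    dose_param = if (is.na(net$dose_param)) NULL else net$dose_param,
    parameters = as.list(net$params),
    provenance = as.list(net$provenance),
    init = net$init,
    reactions = lapply(net$reactions, function(r) {
      list(name = r$name, rate = r$rate,
           reactants = r$reactants, products = r$products,
           factors = lapply(r$factors, function(f)
             Filter(Negate(is.null),
                    f[c("type", "source", "source2", "K", "h", "n")])))
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a model specification from JSON
#' @param path JSON file written by [write_model_json()].
#' @return a `ReactionNetwork` (validated on construction).
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path)
  need <- c("species", "reactions", "parameters", "omega")
  miss <- setdiff(need, names(doc))
  if (length(miss))
    stop("model JSON is missing required keys: ", paste(miss, collapse = ", "))
  reactions <- lapply(doc$reactions, function(r) {
    list(name = r$name, rate = r$rate,
         reactants = lapply(r$reactants, as.numeric),
         products = lapply(r$products, as.numeric),
         factors = lapply(r$factors, function(f) f))
  })
  dp <- doc$dose_param
  dp <- if (is.null(dp) || !length(dp)) NA_character_ else as.character(dp)
  reaction_network(unlist(doc$species), reactions,
                   unlist(doc$parameters), doc$omega,
                   variant = doc$variant %||% "custom",
                   dose_param = dp,
                   init = doc$init %||% list(),
                   provenance = unlist(doc$provenance))
}

#' Write a Gaussian ensemble (mean + covariance) to disk
#' @param ens a `GaussianEnsemble`.
#' @param dir output directory (created if needed); writes `mean.csv`,
#'   `cov.csv` and `meta.json`.
#' @export
write_ensemble <- function(ens, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(data.frame(coord = names(ens$mean) %||%
                         seq_along(ens$mean), mean = ens$mean),
            file.path(dir, "mean.csv"), row.names = FALSE)
  write.csv(ens$cov, file.path(dir, "cov.csv"), row.names = FALSE)
  jsonlite::write_json(list(omega = ens$omega, coords = ens$coords,
                            times = ens$schedule$times,
                            params = as.list(ens$params)),
                       file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a multiplexing report (JSON + CSV table)
#' @param report a `MultiplexingReport`.
#' @param path output JSON path; a sibling `.csv` is written as well.
#' @export
write_mx_report <- function(report, path) {
  jsonlite::write_json(list(ordering = report$signals, v = report$v,
                            MX = report$MX, dkl = as.list(report$dkl),
                            singular_values = report$sv,
                            units = if (isTRUE(report$bits)) "bits" else "nats"),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.csv(data.frame(k = seq_along(report$v), signal = report$signals,
                       v = report$v, MX = report$MX),
            sub("\\.json$", ".csv", path), row.names = FALSE)
  invisible(path)
}

#' Write simulated samples in long format
#' @param samples array `n x species x q` from [pclna_simulate()] /
#'   [ssa_ensemble()].
#' @param times scheduled times.
#' @param path output CSV.
#' @export
write_samples_csv <- function(samples, times, path) {
  dn <- dimnames(samples)[[2]]
  df <- expand.grid(sample = seq_len(dim(samples)[1]), species = dn,
                    phase = seq_len(dim(samples)[3]),
                    KEEP.OUT.ATTRS = FALSE)
  df$time <- times[df$phase]
  df$value <- as.vector(samples)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
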