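# Synthetic gas-exchange/fluorescence series: the model's ETR, A and NPQ
# sampled every 30 s with additive Gaussian noise per replicate, emulating
# the replicated measurement design (3 plants per variety and protocol).

#' Construct an observed series
#'
#' A replicate-resolved time series of the three measured quantities on a
#' common sampling grid, in long format.
#'
#' @param times sample times, s.
#' @param replicate replicate index per row.
#' @param ETR,A,NPQ measured values per row.
#' @param protocol the [light_constant()]/[light_square()] protocol under
#'   which the series was recorded.
#' @param variety optional label.
#' @return data.frame of class \code{"observed_series"} with columns
#'   \code{time_s}, \code{replicate}, \code{ETR}, \code{A}, \code{NPQ};
#'   protocol and variety stored as attributes.
#' @export
observed_series <- function(times, replicate, ETR, A, NPQ, protocol,
                            variety = NA_character_) {
  stopifnot(inherits(protocol, "light_protocol"))
  out <- data.frame(time_s = times, replicate = replicate,
                    ETR = ETR, A = A, NPQ = NPQ)
  if (nrow(out) < 1 || length(unique(out$replicate)) < 1)
    stop("observed series needs at least one replicate")
  class(out) <- c("observed_series", "data.frame")
  attr(out, "protocol") <- protocol
  attr(out, "variety") <- variety
  out
}

#' Replicate-mean observed values
#'
#' @param data an \code{observed_series}.
#' @return data.frame \code{time_s}, \code{ETR}, \code{A}, \code{NPQ} with
#'   quantities averaged over replicates at each time.
#' @export
replicate_means <- function(data) {
  agg <- stats::aggregate(data[c("ETR", "A", "NPQ")],
                          by = list(time_s = data$time_s), FUN = mean)
  agg[order(agg$time_s), ]
}

# Run a block of code with a private RNG stream so callers' RNG state is
# untouched and a given seed always yields the same draws.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic observed series
#'
#' Simulates the model ("truth"), samples ETR, A and NPQ on the measurement
#' grid, and adds independent Gaussian noise per replicate and quantity.
#' Default noise standard deviations (ETR 5, A 1, NPQ 0.1) mimic the visible
#' standard-error bands of the published replicate means. Negative noisy
#' samples are kept: real gas-exchange noise does go negative around zero
#' signal. Deterministic given \code{seed}.
#'
#' @param params a [leaf_params()] truth set.
#' @param protocol light protocol.
#' @param duration series length, s (default 3600).
#' @param sampling_step sampling interval, s (default 30, the saturating
#'   flash schedule).
#' @param noise_sd named vector of per-quantity noise SDs.
#' @param n_reps number of replicates (default 3).
#' @param seed integer RNG seed.
#' @param variety optional label.
#' @return an [observed_series()]; the truth parameters are attached as
#'   attribute \code{"truth"}.
#' @examples
#' obs <- generate_observed(leaf_params("eiko"), light_square(780, 520, 120),
#'                          duration = 600, seed = 1)
#' head(obs)
#' @export
generate_observed <- function(params, protocol, duration = 3600,
                              sampling_step = 30,
                              noise_sd = c(ETR = 5, A = 1, NPQ = 0.1),
                              n_reps = 3, seed = 1,
                              variety = NA_character_) {
  stopifnot(all(noise_sd >= 0), n_reps >= 1)
  for (q in c("ETR", "A", "NPQ"))
    if (!q %in% names(noise_sd)) stop("noise_sd must name ", q)
  sim <- simulate_leaf(params, protocol, duration,
                       output_step = sampling_step)
  truth <- sim$fluxes[, c("ETR", "A", "NPQ")]
  n <- nrow(truth)
  noisy <- .with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_reps), function(r) {
      data.frame(time_s = sim$times, replicate = r,
                 ETR = truth[, "ETR"] + stats::rnorm(n, 0, noise_sd[["ETR"]]),
                 A = truth[, "A"] + stats::rnorm(n, 0, noise_sd[["A"]]),
                 NPQ = truth[, "NPQ"] + stats::rnorm(n, 0, noise_sd[["NPQ"]]))
    }))
  })
  out <- observed_series(noisy$time_s, noisy$replicate, noisy$ETR, noisy$A,
                         noisy$NPQ, protocol, variety)
  attr(out, "truth") <- params
  attr(out, "seed") <- seed
  out
}

#' Read and write observed series as CSV
#'
#' Long-format CSV with columns \code{time_s}, \code{replicate}, \code{ETR},
#' \code{A}, \code{NPQ}; values are written with 17 significant digits so a
#' round trip is bit-identical. The protocol is echoed to a JSON sidecar
#' (\code{<path>.json}) and restored on read when present.
#'
#' @param data an \code{observed_series}.
#' @param path CSV file path.
#' @return \code{read_observed_csv} returns an \code{observed_series} (or a
#'   plain data.frame when no sidecar exists); \code{write_observed_csv}
#'   returns \code{path} invisibly.
#' @export
write_observed_csv <- function(data, path) {
  df <- as.data.frame(data)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 17, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  proto <- attr(data, "protocol")
  if (!is.null(proto)) {
    side <- list(protocol = unclass(proto),
                 variety = attr(data, "variety"),
                 seed = attr(data, "seed"))
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_observed_csv
#' @export
read_observed_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "replicate", "ETR", "A", "NPQ")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("malformed observed-series CSV '", path, "': missing column(s) ",
         paste(missing, collapse = ", "))
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) return(df)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  p <- side$protocol
  proto <- if (p$kind == "constant") {
    light_constant(p$level, flash_boost = isTRUE(p$flash_boost))
  } else {
    light_square(p$high, p$low, p$period, p$duty, p$phase,
                 flash_boost = isTRUE(p$flash_boost))
  }
  out <- observed_series(df$time_s, df$replicate, df$ETR, df$A, df$NPQ,
                         proto, side$variety)
  attr(out, "seed") <- side$seed
  out
}

#' Write the bundled synthetic fixture suite
#'
#' Four synthetic observed-series CSVs — each variety under the constant
#' (650, 60 min) and fluctuating (780/520, 1-min period) measurement
#' protocols, 3 replicates sampled every 30 s — plus the truth parameter
#' JSONs. Seeds are derived deterministically from \code{seed}.
#'
#' @param out_dir writable directory (created if needed).
#' @param seed base RNG seed.
#' @return invisibly, the paths written.
#' @export
make_fixture_suite <- function(out_dir, seed = 20220128) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  protos <- list(constant = light_constant(650),
                 fluct = light_square(780, 520, period = 120))
  paths <- character(0)
  k <- 0L
  for (v in c("eiko", "minngold")) {
    pfile <- file.path(out_dir, paste0(v, "_params.json"))
    write_params(leaf_params(v), pfile)
    paths <- c(paths, pfile)
    for (pn in names(protos)) {
      k <- k + 1L
      obs <- generate_observed(leaf_params(v), protos[[pn]],
                               seed = seed + k, variety = v)
      f <- file.path(out_dir, sprintf("%s_%s_synthetic.csv", v, pn))
      write_observed_csv(obs, f)
      paths <- c(paths, f)
    }
  }
  invisible(paths)
}
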