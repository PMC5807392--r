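raster_groups <- c("communal", "dominant", "subordinate")

#' Behavioral response raster
#'
#' A binary animals-by-stimuli matrix of M-cell mediated escape responses
#' (1 = escape) with per-animal group and stimulation-frequency metadata,
#' and an optional latency matrix (ms, defined only where a response
#' occurred).  The standard habituation protocol delivers 40 stimuli.
#'
#' @param responses integer/logical matrix (animals x stimuli) of 0/1.
#' @param group character vector, one of `"communal"`, `"dominant"`,
#'   `"subordinate"` per animal.
#' @param frequency_hz stimulation frequency per animal (Hz).
#' @param animal_id optional animal identifiers.
#' @param latency optional latency matrix (ms), same shape as `responses`,
#'   NA wherever `responses` is 0.
#' @return An object of class `response_raster`.
#' @export
response_raster <- function(responses, group, frequency_hz,
                            animal_id = NULL, latency = NULL) {
  responses <- as.matrix(responses)
  if (!all(responses %in% c(0, 1))) stop("responses must be 0/1")
  storage.mode(responses) <- "integer"
  dimnames(responses) <- NULL
  n <- nrow(responses)
  if (length(group) == 1) group <- rep(group, n)
  if (length(frequency_hz) == 1) frequency_hz <- rep(frequency_hz, n)
  if (length(group) != n || length(frequency_hz) != n) {
    stop("group and frequency_hz must have one entry per animal")
  }
  bad <- !group %in% raster_groups
  if (any(bad)) {
    stop("unknown group(s): ", paste(unique(group[bad]), collapse = ", "))
  }
  if (is.null(animal_id)) animal_id <- sprintf("a%03d", seq_len(n))
  if (!is.null(latency)) {
    latency <- as.matrix(latency)
    dimnames(latency) <- NULL
    if (!identical(dim(latency), dim(responses))) {
      stop("latency matrix must match the response matrix shape")
    }
    if (any(!is.na(latency) & responses == 0)) {
      stop("latency defined for non-response trials")
    }
  }
  structure(list(animal_id = animal_id, group = group,
                 frequency_hz = frequency_hz, responses = responses,
                 latency = latency),
            class = "response_raster")
}

#' @export
print.response_raster <- function(x, ...) {
  cat(sprintf("response raster: %d animals x %d stimuli (%s)\n",
              nrow(x$responses), ncol(x$responses),
              paste(sprintf("%s n=%d", names(table(x$group)), table(x$group)),
                    collapse = ", ")))
  invisible(x)
}

#' Read / write a response raster as CSV
#'
#' The schema is one row per animal with columns `animal_id`, `group`,
#' `frequency_hz`, `s01..sNN` (binary responses) and optionally
#' `lat01..latNN` (latencies, ms).  Malformed rows are rejected with their
#' row and column named.
#'
#' @param path CSV file path.
#' @return `read_raster()` returns a `response_raster`;
#'   `write_raster()` returns `path` invisibly.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse raster CSV: ",
                                          conditionMessage(e)))
  if (nrow(df) == 0) stop("raster file contains no animals: ", path)
  need <- c("animal_id", "group", "frequency_hz")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  scol <- grep("^s[0-9]+$", names(df), value = TRUE)
  if (length(scol) == 0) stop("no stimulus columns (s01..sNN) found")
  scol <- scol[order(as.integer(sub("^s", "", scol)))]
  resp <- as.matrix(df[scol])
  bad <- which(!(resp %in% c(0, 1)) | is.na(resp), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-binary response value at row %d, column %s",
                 bad[1, 1], scol[bad[1, 2]]))
  }
  lcol <- grep("^lat[0-9]+$", names(df), value = TRUE)
  lat <- NULL
  if (length(lcol)) {
    if (length(lcol) != length(scol)) {
      stop("latency columns do not match stimulus columns")
    }
    lcol <- lcol[order(as.integer(sub("^lat", "", lcol)))]
    lat <- as.matrix(df[lcol])
  }
  response_raster(resp, df$group, df$frequency_hz,
                  animal_id = as.character(df$animal_id), latency = lat)
}

#' @rdname read_raster
#' @param raster a `response_raster`.
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "response_raster"))
  ns <- ncol(raster$responses)
  resp <- as.data.frame(raster$responses)
  names(resp) <- sprintf("s%02d", seq_len(ns))
  df <- cbind(data.frame(animal_id = raster$animal_id, group = raster$group,
                         frequency_hz = raster$frequency_hz), resp)
  if (!is.null(raster$latency)) {
    lat <- as.data.frame(raster$latency)
    names(lat) <- sprintf("lat%02d", seq_len(ns))
    df <- cbind(df, lat)
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Binned percent-response summary
#'
#' Bin consecutive stimuli (default 2 per bin: at 1 Hz this is the 2 s
#' binning, at 0.2 Hz the 10 s binning of the standard summaries), compute
#' each animal's percent response per bin, and summarise per group as mean
#' over animals with SEM (`sd/sqrt(n)`).
#'
#' @param raster a `response_raster`.
#' @param stimuli_per_bin bin width in stimuli; must divide the stimulus
#'   count.
#' @return Data frame with columns `group`, `bin`, `mean_percent`, `sem`,
#'   `n`.
#' @export
binned_percent_response <- function(raster, stimuli_per_bin = 2) {
  stopifnot(inherits(raster, "response_raster"))
  ns <- ncol(raster$responses)
  if (ns %% stimuli_per_bin != 0) {
    stop("stimuli_per_bin must divide the stimulus count (", ns, ")")
  }
  nb <- ns %/% stimuli_per_bin
  bin_of <- rep(seq_len(nb), each = stimuli_per_bin)
  per_animal <- t(apply(raster$responses, 1, function(r) {
    tapply(r, bin_of, mean) * 100
  }))
  out <- do.call(rbind, lapply(split(seq_len(nrow(per_animal)), raster$group),
                               function(rows) {
    m <- per_animal[rows, , drop = FALSE]
    data.frame(group = raster$group[rows[1]], bin = seq_len(nb),
               mean_percent = colMeans(m),
               sem = apply(m, 2, sd) / sqrt(nrow(m)),
               n = nrow(m))
  }))
  rownames(out) <- NULL
  out
}

#' Pooled five-stimulus block response rates
#'
#' Pool stimuli into consecutive blocks (default 5: stimuli 1--5, 6--10,
#' ...) and report the mean response rate per group and block.  With the
#' standard 40-stimulus protocol this gives 8 blocks; habituation shows as
#' block 1 exceeding the later blocks.
#'
#' @param raster a `response_raster`.
#' @param block block width in stimuli; must divide the stimulus count.
#' @return Data frame with columns `group`, `block`, `rate`, `n`.
#' @export
pooled_block_rates <- function(raster, block = 5) {
  stopifnot(inherits(raster, "response_raster"))
  ns <- ncol(raster$responses)
  if (ns %% block != 0) stop("block must divide the stimulus count (", ns, ")")
  nb <- ns %/% block
  blk <- rep(seq_len(nb), each = block)
  out <- do.call(rbind, lapply(split(seq_len(nrow(raster$responses)),
                                     raster$group), function(rows) {
    m <- raster$responses[rows, , drop = FALSE]
    data.frame(group = raster$group[rows[1]], block = seq_len(nb),
               rate = as.numeric(tapply(colMeans(m), blk, mean)),
               n = length(rows))
  }))
  rownames(out) <- NULL
  out
}

#' Default habituation profiles for the synthetic raster generator
#'
#' Exponential-plateau Bernoulli profiles per group: response probability
#' at stimulus k (0-based) is `plateau + (p0 - plateau) * exp(-k/decay)`.
#' At 1 Hz dominant-like animals habituate fast to a low plateau and
#' subordinate-like animals keep a high plateau; at 0.2 Hz all plateaus
#' rise, shrinking the group differences -- mirroring the empirical
#' ordering and frequency effect.
#'
#' @param frequency stimulation frequency (Hz); profiles are defined for 1
#'   and 0.2 Hz, other frequencies fall back to the 1 Hz set.
#' @return Named list of per-group profiles `list(p0, plateau, decay)`.
#' @export
default_profiles <- function(frequency = 1) {
  plateaus <- if (isTRUE(all.equal(frequency, 0.2))) {
    c(dominant = 0.45, communal = 0.55, subordinate = 0.70)
  } else {
    c(dominant = 0.05, communal = 0.25, subordinate = 0.55)
  }
  decays <- c(dominant = 3, communal = 4, subordinate = 5)
  lapply(setNames(nm = raster_groups), function(g) {
    list(p0 = 1, plateau = unname(plateaus[g]), decay = unname(decays[g]))
  })
}

#' Generate a synthetic habituation raster
#'
#' Seeded Bernoulli generator emulating status-dependent habituation:
#' each animal responds to stimulus k (0-based) with probability
#' `plateau + (p0 - plateau) * exp(-k/decay)` of its group profile.
#' Latencies for responded trials are drawn from a normal distribution
#' (mean `latency_mean`, sd `latency_sd`, truncated at 0.1 ms).
#'
#' @param profiles per-group profiles as from [default_profiles()].
#' @param n_animals animals per group.
#' @param n_stimuli stimuli per animal.
#' @param frequency stimulation frequency stored in the raster (and used
#'   to pick default profiles).
#' @param seed RNG seed; identical seeds give identical rasters.  The
#'   caller's RNG state is restored afterwards.
#' @param latencies also generate a latency matrix.
#' @param latency_mean,latency_sd latency distribution (ms).
#' @return A `response_raster`.
#' @examples
#' r <- generate_raster(n_animals = 5, seed = 1)
#' pooled_block_rates(r)
#' @export
generate_raster <- function(profiles = default_profiles(frequency),
                            n_animals = 20, n_stimuli = 40, frequency = 1,
                            seed = NULL, latencies = FALSE,
                            latency_mean = 5.7, latency_sd = 1) {
  for (g in names(profiles)) {
    pr <- profiles[[g]]
    if (pr$p0 < 0 || pr$p0 > 1 || pr$plateau < 0 || pr$plateau > 1) {
      stop("p0 and plateau must lie in [0, 1] (group ", g, ")")
    }
    if (pr$decay <= 0) stop("decay constant must be > 0 (group ", g, ")")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  k <- seq_len(n_stimuli) - 1
  groups <- names(profiles)
  resp <- NULL; lat <- NULL; grp <- character(0); ids <- character(0)
  for (g in groups) {
    pr <- profiles[[g]]
    p <- pr$plateau + (pr$p0 - pr$plateau) * exp(-k / pr$decay)
    m <- matrix(rbinom(n_animals * n_stimuli, 1, rep(p, each = n_animals)),
                nrow = n_animals)
    resp <- rbind(resp, m)
    if (latencies) {
      lm <- matrix(NA_real_, n_animals, n_stimuli)
      nresp <- sum(m == 1)
      lm[m == 1] <- pmax(0.1, rnorm(nresp, latency_mean, latency_sd))
      lat <- rbind(lat, lm)
    }
    grp <- c(grp, rep(g, n_animals))
    ids <- c(ids, sprintf("%s%03d", substr(g, 1, 3), seq_len(n_animals)))
  }
  response_raster(resp, grp, frequency, animal_id = ids, latency = lat)
}

#' Per-group latency summary
#'
#' Mean and SEM of response latencies pooled over all responded trials
#' within each group.  With a single responded trial the SEM is reported
#' as 0 and flagged (`single_obs`), rather than propagating NA.
#'
#' @param raster a `response_raster` with a latency matrix.
#' @return Data frame with columns `group`, `mean_ms`, `sem`, `n`,
#'   `single_obs`.
#' @export
latency_summary <- function(raster) {
  stopifnot(inherits(raster, "response_raster"))
  if (is.null(raster$latency)) stop("raster has no latency matrix")
  out <- do.call(rbind, lapply(split(seq_along(raster$group), raster$group),
                               function(rows) {
    x <- raster$latency[rows, , drop = FALSE]
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      stop("group ", raster$group[rows[1]], " has no responded trials")
    }
    data.frame(group = raster$group[rows[1]], mean_ms = mean(x),
               sem = if (length(x) > 1) sd(x) / sqrt(length(x)) else 0,
               n = length(x), single_obs = length(x) == 1)
  }))
  rownames(out) <- NULL
  out
}

#' Fit the exponential-plateau habituation profile
#'
#' Least-squares fit of `plateau + (p0 - plateau) * exp(-k/decay)` to the
#' per-stimulus group-mean response rates (k 0-based), one fit per group.
#' Used to check that generator parameters are recoverable from the
#' rasters it produces.
#'
#' @param raster a `response_raster`.
#' @return Data frame with columns `group`, `p0`, `plateau`, `decay`.
#' @export
fit_habituation_profile <- function(raster) {
  stopifnot(inherits(raster, "response_raster"))
  k <- seq_len(ncol(raster$responses)) - 1
  out <- do.call(rbind, lapply(split(seq_along(raster$group), raster$group),
                               function(rows) {
    rate <- colMeans(raster$responses[rows, , drop = FALSE])
    start <- list(p0 = min(max(rate[1], 0.05), 1),
                  plateau = min(max(mean(tail(rate, 10)), 0.01), 0.99),
                  decay = 3)
    fit <- nls(rate ~ plateau + (p0 - plateau) * exp(-k / decay),
               data = data.frame(rate = rate, k = k), start = start,
               algorithm = "port",
               lower = c(p0 = 0, plateau = 0, decay = 0.1),
               upper = c(p0 = 1, plateau = 1, decay = 200))
    est <- coef(fit)
    data.frame(group = raster$group[rows[1]], p0 = est[["p0"]],
               plateau = est[["plateau"]], decay = est[["decay"]])
  }))
  rownames(out) <- NULL
  out
}
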