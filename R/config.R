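#' Default analysis configuration
#'
#' Nested list of every tunable analysis parameter, mirrored one-to-one by
#' the flat `key = value` text format of [read_config()] (keys like
#' `epoch.overlap.bicoherence`). Defaults: 1-45 Hz zero-phase Hamming FIR,
#' 2-s epochs with 25 percent overlap (75 percent for bicoherence), a 2-s
#' edge-transient guard per segment, 1-Hz / 2-Hz wavelet grid, mean FIWBIC
#' aggregation, 50 percent Welch overlap for coherence, ApEn/SaEn m = 2 and
#' r = 0.2 SD, PeEn order 3 lag 2 in nats, 5-level db4 normalized WaEn, and
#' stratified BH-FDR with pooled-variance t-tests.
#'
#' @return Nested configuration list.
#' @export
qeeg_config <- function() {
  list(
    filter = list(low_hz = 1, high_hz = 45),
    epoch = list(length_s = 2, trim_s = 2,
                 overlap = list(spectral = 0.25, bicoherence = 0.75,
                                coherence = 0.25, entropy = 0.25)),
    cwt = list(step_hz = 1, bandwidth_hz = 2),
    fiwbic = list(aggregate = "mean"),
    coh = list(window_overlap = 0.5),
    ent = list(estimators = c("apen", "saen", "peen", "waen"),
               apen = list(m = 2L, r_frac = 0.2),
               saen = list(m = 2L, r_frac = 0.2),
               peen = list(order = 3L, delay = 2L, log_base = exp(1)),
               waen = list(levels = 5L, mother = "db4", normalized = TRUE)),
    stats = list(fdr_scope = "family", alpha = 0.05, var_equal = TRUE)
  )
}

# set a nested list element from a dotted key
.set_by_key <- function(cfg, key, value) {
  path <- strsplit(key, ".", fixed = TRUE)[[1]]
  node <- cfg
  ref <- list()
  # walk down; rebuild on the way up
  assign_rec <- function(node, path, value) {
    if (length(path) == 1L) {
      old <- node[[path]]
      if (is.numeric(old)) {
        v <- suppressWarnings(as.numeric(value))
        if (is.na(v)) stop("numeric value expected for ", key)
        if (is.integer(old)) v <- as.integer(v)
        node[[path]] <- v
      } else if (is.logical(old)) {
        node[[path]] <- as.logical(value)
      } else {
        node[[path]] <- strsplit(value, ",", fixed = TRUE)[[1]]
      }
      return(node)
    }
    if (is.null(node[[path[1]]])) stop("unknown config key: ", key)
    node[[path[1]]] <- assign_rec(node[[path[1]]], path[-1], value)
    node
  }
  assign_rec(cfg, path, value)
}

#' Read a flat key/value configuration file
#'
#' Lines of the form `key = value` with dotted keys (e.g.
#' `filter.low_hz = 1`, `ent.peen.order = 3`); `#` starts a comment. Values
#' override the defaults of [qeeg_config()]; unknown keys are an error.
#'
#' @param path configuration file.
#' @param base configuration list to override.
#' @return Configuration list.
#' @export
read_config <- function(path, base = qeeg_config()) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed config line: ", ln)
    key <- trimws(substr(ln, 1L, eq - 1L))
    val <- trimws(substring(ln, eq + 1L))
    base <- .set_by_key(base, key, val)
  }
  base
}

# small FNV-1a style hash of the deparsed config, for provenance stamping
config_hash <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # multiply mod 2^32 without losing double precision
    hi16 <- h %/% 65536
    lo16 <- h %% 65536
    h <- (lo16 * p + ((hi16 * p) %% 65536) * 65536) %% 2^32
  }
  sprintf("%08x", h)
}
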