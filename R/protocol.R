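#' Library-preparation protocol configuration
#'
#' Describes how a synthetic sequencing library is built. Three protocol
#' families are supported, mirroring common RNA-seq chemistry:
#' \describe{
#'   \item{truseq}{mRNA is fragmented first; the only amplification is the
#'     PCR of the final sequencing library, so every PCR copy shares both
#'     fragment ends with its template.}
#'   \item{smartseq}{full-length cDNA is pre-amplified and only then
#'     fragmented (tagmentation); pre-amplification copies are fragmented
#'     independently and therefore leave no coordinate fingerprint.}
#'   \item{umiseq}{like smartseq but each molecule receives a unique
#'     molecular identifier (UMI) and a sample barcode before
#'     pre-amplification, and fragments are retained only near the 3' end
#'     of the transcript.}
#' }
#'
#' @param protocol One of \code{"truseq"}, \code{"smartseq"},
#'   \code{"umiseq"}.
#' @param read_length Read length in bases.
#' @param paired Paired-end sequencing? Defaults to \code{TRUE} except for
#'   umiseq (single cDNA read).
#' @param preamp_cycles Pre-amplification PCR cycles (must be 0 for
#'   truseq). Defaults: 0 (truseq), 9 (smartseq), 15 (umiseq).
#' @param library_cycles Library PCR cycles. Defaults: 15 (truseq), 12
#'   (smartseq, umiseq).
#' @param pcr_efficiency Per-fragment, per-cycle duplication probability in
#'   [0, 1].
#' @param fragmentation_mode \code{"uniform"} or \code{"hotspot"}.
#' @param hotspot_concentration Symmetric Dirichlet concentration for
#'   per-position break weights; small values concentrate breaks on few
#'   hotspots (roughly, the effective number of break sites shrinks by a
#'   factor \code{1 + 1/concentration}).
#' @param umi_length UMI length in bases (> 0 only for umiseq).
#' @param barcode_length Sample-barcode length (umiseq).
#' @param target_depth Number of read (pairs) to sample from the amplified
#'   library.
#' @param fragment_mean,fragment_sd Fragment-size distribution (bases).
#' @param three_prime_window For umiseq, fragments are kept only if their 3'
#'   end falls within this many bases of the transcript 3' end.
#' @param seed Optional integer seed used by \code{\link{simulate_library}}.
#' @return A validated list of class \code{protocol_config}.
#' @examples
#' protocol_config("truseq", target_depth = 1e4)
#' protocol_config("umiseq", umi_length = 8)
#' @export
protocol_config <- function(protocol = c("truseq", "smartseq", "umiseq"),
                            read_length = 50L,
                            paired = NULL,
                            preamp_cycles = NULL,
                            library_cycles = NULL,
                            pcr_efficiency = 0.5,
                            fragmentation_mode = c("uniform", "hotspot"),
                            hotspot_concentration = 1,
                            umi_length = NULL,
                            barcode_length = 8L,
                            target_depth = 10000L,
                            fragment_mean = 300,
                            fragment_sd = 60,
                            three_prime_window = 600L,
                            seed = NULL) {
  protocol <- match.arg(protocol)
  fragmentation_mode <- match.arg(fragmentation_mode)
  paired <- paired %||% (protocol != "umiseq")
  preamp_cycles <- preamp_cycles %||%
    switch(protocol, truseq = 0L, smartseq = 9L, umiseq = 15L)
  library_cycles <- library_cycles %||%
    switch(protocol, truseq = 15L, smartseq = 12L, umiseq = 12L)
  umi_length <- umi_length %||% switch(protocol, umiseq = 10L, 0L)

  cfg <- list(protocol = protocol,
              read_length = as.integer(read_length),
              paired = isTRUE(paired),
              preamp_cycles = as.integer(preamp_cycles),
              library_cycles = as.integer(library_cycles),
              pcr_efficiency = as.numeric(pcr_efficiency),
              fragmentation_mode = fragmentation_mode,
              hotspot_concentration = as.numeric(hotspot_concentration),
              umi_length = as.integer(umi_length),
              barcode_length = as.integer(barcode_length),
              target_depth = as.integer(target_depth),
              fragment_mean = as.numeric(fragment_mean),
              fragment_sd = as.numeric(fragment_sd),
              three_prime_window = as.integer(three_prime_window),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  class(cfg) <- "protocol_config"
  validate_protocol_config(cfg)
  cfg
}

validate_protocol_config <- function(cfg) {
  stopifnot(inherits(cfg, "protocol_config"))
  if (cfg$pcr_efficiency < 0 || cfg$pcr_efficiency > 1)
    stopf("pcr_efficiency must lie in [0, 1]")
  if (cfg$protocol == "truseq" && cfg$preamp_cycles != 0L)
    stopf("truseq has no pre-amplification: preamp_cycles must be 0")
  if (cfg$umi_length > 0L && cfg$protocol != "umiseq")
    stopf("umi_length > 0 requires protocol = 'umiseq'")
  if (cfg$protocol == "umiseq" && cfg$umi_length <= 0L)
    stopf("umiseq requires umi_length > 0")
  if (cfg$read_length < 1L) stopf("read_length must be positive")
  if (cfg$target_depth < 1L) stopf("target_depth must be positive")
  if (cfg$hotspot_concentration <= 0)
    stopf("hotspot_concentration must be positive")
  if (cfg$preamp_cycles < 0L || cfg$library_cycles < 0L)
    stopf("cycle counts must be non-negative")
  invisible(cfg)
}

#' Read or write a protocol configuration as YAML
#'
#' @param cfg A \code{protocol_config}.
#' @param path File path.
#' @return \code{read_protocol_config} returns a \code{protocol_config}.
#' @export
write_protocol_config <- function(cfg, path) {
  validate_protocol_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_protocol_config
#' @export
read_protocol_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(protocol_config, raw)
}
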