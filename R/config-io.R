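#' Write a parameter bundle to a structured text configuration file
#'
#' The configuration format is JSON with nested sections mirroring the
#' parameter types. Doubles are written with 17 significant digits so that
#' a write/read round trip reproduces every value bit-exactly.
#'
#' @param bundle A `cvr_bundle`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_config()]
#' @export
write_config <- function(bundle, path) {
  strip <- function(x) {
    if (is.list(x)) {
      structure(lapply(x, strip), names = names(x))
    } else if (!is.null(names(x))) {
      as.list(x)  # keep names of atomic vectors as JSON object keys
    } else {
      x
    }
  }
  json <- jsonlite::toJSON(strip(unclass(bundle)), auto_unbox = TRUE,
                           digits = I(17), null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a parameter bundle from a configuration file
#'
#' @param path Path to a file written by [write_config()].
#' @return A `cvr_bundle`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::fromJSON(readLines(path), simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  # whole numbers parse as integer; the containers carry doubles throughout
  raw <- rapply(raw, as.numeric, classes = "integer", how = "replace")
  ch <- function(p) chamber_params(E_es = p$E_es, V_d = p$V_d, V_0 = p$V_0,
                                   lam = p$lam, P_0 = p$P_0)
  vs <- function(p) vessel_params(E = p$E, V_d = p$V_d, in_thorax = p$in_thorax)
  vl <- function(p) valve_params(R = p$R, L = p$L)
  bundle <- list(
    name = raw$name, model = raw$model,
    walls = lapply(raw$walls, ch),
    vessels = lapply(raw$vessels, vs),
    circulation = circulation_params(
      valves = lapply(raw$circulation$valves, vl),
      R_pul = raw$circulation$R_pul, R_sys = raw$circulation$R_sys,
      V_tot = raw$circulation$V_tot,
      P_pl_const = raw$circulation$P_pl_const),
    driver = driver_config(N = raw$driver$N, A = raw$driver$A,
                           B = raw$driver$B, C = raw$driver$C,
                           A_hat = raw$driver$A_hat, B_hat = raw$driver$B_hat,
                           C_hat = raw$driver$C_hat, hr = raw$driver$hr),
    respiratory = if (!is.null(raw$respiratory)) {
      do.call(respiratory_params, raw$respiratory)
    },
    initial = initial_conditions(
      volumes = unlist(raw$initial$volumes),
      flows = if (!is.null(raw$initial$flows)) unlist(raw$initial$flows),
      x = raw$initial$x, y = raw$initial$y, P_mus = raw$initial$P_mus,
      V_alv = raw$initial$V_alv, s = raw$initial$s)
  )
  structure(bundle, class = "cvr_bundle")
}
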