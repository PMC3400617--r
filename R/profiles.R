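# Vector profiles: verbatim flank/overhang strings that turn a design into a
# clonable annealed duplex for one backbone. Built-ins ship as a YAML file.

PROFILE_ALIASES <- c(
  "plvx-shrna2" = "plvx-shRNA2", "plvx_shrna2" = "plvx-shRNA2",
  "plvx-shRNA2" = "plvx-shRNA2",
  "psicheck" = "psicheck", "psiCHECK" = "psicheck",
  "pmir" = "pmir-report", "pmir-report" = "pmir-report",
  "pMIR" = "pmir-report", "pMIR-Report" = "pmir-report"
)

profile_registry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "vector_profiles.yaml", package = "starmiR")
      cfg <- yaml::read_yaml(path)
      cache <<- cfg$profiles
    }
    cache
  }
})

#' List built-in vector profiles
#'
#' @return Named list of profile definitions (see [vector_profile()]).
#' @export
vector_profiles <- function() {
  lapply(stats::setNames(names(profile_registry()), names(profile_registry())),
         vector_profile)
}

#' Look up (or validate) a vector profile
#'
#' A profile defines how a design core becomes an annealing-ready duplex:
#' `top = top_prefix + core_prefix + core + core_suffix`;
#' `bottom = bottom_prefix + revcomp(core_prefix + core + core_suffix) +
#' bottom_suffix`. The prefixes are the single-stranded 5' overhangs after
#' annealing. Built-ins: `plvx-shRNA2` (BamHI/EcoRI overexpression backbone),
#' `psicheck` (XhoI/NotI sensor), `pmir-report` (MluI/SacI sensor).
#'
#' @param profile a profile name (case-insensitive aliases accepted, e.g.
#'   `"pMIR"`) or a list with the required fields.
#' @return Object of class `vector_profile`.
#' @examples
#' vector_profile("plvx-shRNA2")
#' @export
vector_profile <- function(profile) {
  if (is.character(profile)) {
    key <- PROFILE_ALIASES[profile]
    if (is.na(key)) key <- PROFILE_ALIASES[tolower(profile)]
    reg <- profile_registry()
    if (is.na(key) || !key %in% names(reg)) {
      stop(sprintf("unknown vector profile '%s' (built-ins: %s)", profile,
                   paste(names(reg), collapse = ", ")), call. = FALSE)
    }
    profile <- c(name = unname(key), reg[[key]])
  }
  required <- c("name", "top_prefix", "core_prefix", "core_suffix",
                "bottom_prefix", "bottom_suffix", "enzymes")
  missing <- setdiff(required, names(profile))
  if (length(missing)) {
    stop("vector profile is missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (f in c("top_prefix", "core_prefix", "core_suffix", "bottom_prefix",
              "bottom_suffix")) {
    val <- profile[[f]]
    if (is.null(val)) val <- ""
    profile[[f]] <- as.character(nt_seq(val, "DNA"))
  }
  structure(profile, class = "vector_profile")
}

#' @export
print.vector_profile <- function(x, ...) {
  cat(sprintf(
    "<vector_profile> %s (%s)\n  top: %s + %s + <core> + %s\n  bottom: %s + revcomp + %s\n",
    x$name, paste(x$enzymes, collapse = "/"), x$top_prefix, x$core_prefix,
    x$core_suffix, x$bottom_prefix, x$bottom_suffix))
  invisible(x)
}
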