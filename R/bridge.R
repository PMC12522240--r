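#' @keywords internal
"_PACKAGE"

# Batched RDKit bridge -------------------------------------------------------
#
# All toolkit-dependent steps (SMILES parsing, canonicalization, Morgan
# fingerprints with per-atom bit provenance, stereoisomer enumeration, graph
# -> SMILES conversion) run in a single python subprocess per call, each call
# carrying an arbitrary number of operations.  Callers batch aggressively:
# one bridge call per pipeline stage, not per molecule.

bridge_python <- function() {
  py <- getOption("sigenum.python", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) {
    stop("No python interpreter found; set options(sigenum.python = ...)")
  }
  py
}

bridge_script <- function() {
  path <- system.file("python", "chembridge.py", package = "sigenum")
  if (!nzchar(path)) {
    # during development (pkgload) inst/ is mapped directly
    path <- file.path("inst", "python", "chembridge.py")
  }
  if (!file.exists(path)) stop("chembridge.py not found")
  path
}

#' Run a batch of operations through the RDKit bridge
#'
#' @param ops list of operation payloads (each a named list with an `op`
#'   field); see `inst/python/chembridge.py` for the protocol.
#' @return list of results, one per operation.
#' @keywords internal
bridge_call <- function(ops) {
  stopifnot(is.list(ops), length(ops) >= 1)
  req <- tempfile(fileext = ".json")
  resp <- tempfile(fileext = ".json")
  on.exit(unlink(c(req, resp)), add = TRUE)
  jsonlite::write_json(
    list(ops = ops), req,
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  status <- system2(
    bridge_python(), c(bridge_script(), req, resp),
    stdout = FALSE, stderr = ""
  )
  if (!identical(status, 0L) || !file.exists(resp)) {
    stop("RDKit bridge failed (exit status ", status, ")")
  }
  jsonlite::read_json(resp)$results
}

# Wrap a vector for auto_unbox-safe JSON: always serialize as array.
json_vec <- function(x) I(x)
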