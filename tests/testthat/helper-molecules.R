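# Shared molecules and alphabets, built once per test run -------------------

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

worked_mol <- function() {
  cached("worked_mol", parse_smiles(worked_example()$smiles)[[1]])
}

worked_alphabet <- function() {
  cached("worked_alphabet", build_alphabet(list(worked_mol())))
}

worked_fp <- function() {
  cached("worked_fp", counted_ecfp(worked_mol()))
}

# a small diverse fixture used by most property tests
fixture_small <- function() {
  cached("fixture_small", generate_fixture_set(40, seed = 11))
}

# the full-size fixture used by the acceptance checks
fixture_full <- function() {
  cached("fixture_full", generate_fixture_set(200, seed = 7))
}

fixture_small_attrib <- function() {
  cached("fixture_small_attrib", attribute_bits(fixture_small()$molecules))
}
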