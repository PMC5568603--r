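# small shared helpers

# evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# rotation matrix for a rotation of `angle` radians about unit `axis`
# (Rodrigues form)
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# md5 digest of an R object via its canonical JSON serialization
config_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = 10, null = "null")
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
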