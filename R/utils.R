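# Small internal geometry helpers shared across modules.

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  L <- .vnorm(v)
  if (L < 1e-300) stop_geometry("cannot normalise a zero-length vector")
  v / L
}

.cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

.bbox_diag <- function(X) {
  r <- apply(X, 2, range)
  .vnorm(r[2, ] - r[1, ])
}

.as_xyz <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 3 || !all(is.finite(p)))
    stop_input(sprintf("%s must be a finite 3D coordinate", what))
  p
}

.as_matrix3 <- function(X, what = "points") {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) != 3) stop_input(sprintf("%s must have 3 columns (x, y, z)", what))
  if (!all(is.finite(X))) stop_input(sprintf("%s contain non-finite coordinates", what))
  X
}

# Error conditions map onto the CLI exit codes: input -> 3, geometry -> 4.
stop_input <- function(msg, ...) {
  stop(structure(class = c("scalplayout_input_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

stop_geometry <- function(msg, ...) {
  stop(structure(class = c("scalplayout_geometry_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

stop_usage <- function(msg, ...) {
  stop(structure(class = c("scalplayout_usage_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# Run code with a temporary RNG seed, restoring global RNG state after.
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seeds derived from one parent seed (kept < 2^31).
.child_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629
}

.log_msg <- function(...) {
  message(sprintf(...))
}
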