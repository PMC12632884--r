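#' @keywords internal
"_PACKAGE"

## The program world: 12 image objects serve as program locations, each
## associated with one of six operations acting on a 3-bit cartoon face.

#' Default object (program location) names
#'
#' Twelve everyday-image identifiers used as program locations.
#' @return character vector of length 12
#' @export
default_locations <- function() {
  c("Newspaper", "Spaceship", "Piano", "Key", "Chemistry", "Broccoli",
    "Anchor", "Elephant", "Mirror", "Book", "Coin", "Web")
}

#' Face attributes and their binary values
#'
#' The face data structure has three orthogonal binary attributes.
#' @return named list mapping attribute -> its two values
#' @export
face_attributes <- function() {
  list(shape = c("round", "spiky"),
       limb  = c("hands", "feet"),
       hat   = c("crown", "fedora"))
}

#' The six operations
#'
#' Every operation is a (type, attribute) pair: `swap` flips the attribute,
#' `branch` selects a successor conditioned on it.
#' @return data.frame with columns `op`, `op_type`, `attribute`
#' @export
operation_table <- function() {
  attrs <- names(face_attributes())
  data.frame(
    op        = c(paste0("swap_", attrs), paste0("branch_", attrs)),
    op_type   = rep(c("swap", "branch"), each = 3L),
    attribute = rep(attrs, 2L),
    stringsAsFactors = FALSE
  )
}

#' Construct a face state
#'
#' @param shape,limb,hat attribute values (see [face_attributes()])
#' @return named character vector with class `face_state`
#' @export
face_state <- function(shape, limb, hat) {
  av <- face_attributes()
  stopifnot(shape %in% av$shape, limb %in% av$limb, hat %in% av$hat)
  structure(c(shape = shape, limb = limb, hat = hat), class = "face_state")
}

#' Enumerate all 8 face states
#'
#' @return list of `face_state` objects (2 x 2 x 2 combinations)
#' @export
all_faces <- function() {
  av <- face_attributes()
  grid <- expand.grid(shape = av$shape, limb = av$limb, hat = av$hat,
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    face_state(grid$shape[i], grid$limb[i], grid$hat[i]))
}

#' Flip one attribute of a face
#'
#' A swap is an involution: applying it twice restores the original value.
#' @param face a `face_state`
#' @param attribute one of `"shape"`, `"limb"`, `"hat"`
#' @return the updated `face_state`
#' @export
flip_attribute <- function(face, attribute) {
  vals <- face_attributes()[[attribute]]
  face[[attribute]] <- setdiff(vals, face[[attribute]])
  structure(face, class = "face_state")
}

#' Hamming distance between two faces (0-3)
#' @param a,b `face_state` objects
#' @export
face_distance <- function(a, b) sum(unclass(a) != unclass(b))

#' Compact string id of a face, e.g. "round.hands.crown"
#' @param face a `face_state`
#' @export
face_id <- function(face) paste(unclass(face), collapse = ".")

## Deterministic seed fan-out. Stage seeds are derived from a master seed and
## a string key so adding a stage never perturbs seeds of existing stages.
#' Derive a stage seed from a master seed and a key
#'
#' @param master integer master seed
#' @param key character key naming the consumer (stage, trial, ...)
#' @return integer seed in `[1, 2^31 - 2]`
#' @export
derive_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L)
  m <- 2147483647 # 2^31 - 1 (prime)
  x <- (abs(as.numeric(master)) %% m)
  for (b in utf8ToInt(as.character(key))) {
    x <- (x * 31 + b) %% m
  }
  as.integer(x %% (m - 2)) + 1L
}
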