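#' Layer specification with exact parameter accounting
#'
#' @param kind One of `"conv1d"`, `"maxpool1d"`, `"global_average_pool"`,
#'   `"dense"`, `"concat"`, `"softmax_output"`.
#' @param units_or_filters Output units (dense) or filters (conv1d); pool size
#'   for `maxpool1d`.
#' @param kernel_size Kernel length for `conv1d`.
#' @param activation `"relu"`, `"softmax"` or `"none"`.
#' @param in_dim Input channels (conv1d) or input units (dense).
#' @return A `layer_spec` with its closed-form trainable-parameter count:
#'   `in_ch * k * filters + filters` for conv1d, `in * out + out` for dense,
#'   0 for pooling and concatenation.
#' @export
layer_spec <- function(kind, units_or_filters = NA_integer_,
                       kernel_size = NA_integer_, activation = "none",
                       in_dim = NA_integer_) {
  param_count <- switch(kind,
    conv1d = in_dim * kernel_size * units_or_filters + units_or_filters,
    dense = in_dim * units_or_filters + units_or_filters,
    maxpool1d = 0L,
    global_average_pool = 0L,
    concat = 0L,
    softmax_output = 0L,
    stop("unknown layer kind: ", kind, call. = FALSE)
  )
  structure(list(kind = kind, units_or_filters = as.integer(units_or_filters),
                 kernel_size = as.integer(kernel_size), activation = activation,
                 in_dim = as.integer(in_dim), param_count = as.integer(param_count)),
            class = "layer_spec")
}

#' The EMG convolutional branch
#'
#' Input 1000 x 7 -> Conv1D(16 filters, kernel 5, ReLU) -> MaxPool(4) ->
#' Conv1D(32 filters, kernel 5, ReLU) -> global average pooling -> 32-dim
#' embedding. The convolutions use valid padding; global average pooling (not
#' flattening) keeps the parameter count independent of the input length.
#' Conv parameter counts: 7*5*16 + 16 = 576 and 16*5*32 + 32 = 2,592.
#'
#' @return List of [layer_spec()].
#' @export
build_emg_branch <- function() {
  list(
    layer_spec("conv1d", units_or_filters = 16, kernel_size = 5,
               activation = "relu", in_dim = 7),
    layer_spec("maxpool1d", units_or_filters = 4),
    layer_spec("conv1d", units_or_filters = 32, kernel_size = 5,
               activation = "relu", in_dim = 16),
    layer_spec("global_average_pool")
  )
}

#' The fully connected context branch
#'
#' Dense(input_dim -> 192, ReLU) -> Dense(192 -> 32, ReLU) embedding. The
#' first layer's width of 192 makes removing one scalar context input change
#' the total parameter count by exactly 192.
#'
#' @param input_dim Context vector dimension (>= 1).
#' @return List of [layer_spec()].
#' @export
build_context_branch <- function(input_dim) {
  if (input_dim < 1) stop("context input_dim must be >= 1", call. = FALSE)
  list(
    layer_spec("dense", units_or_filters = 192, activation = "relu",
               in_dim = input_dim),
    layer_spec("dense", units_or_filters = 32, activation = "relu", in_dim = 192)
  )
}

# Fixed mapping from ablation-variant name to the excluded context variables.
.excluded_vars <- list(
  M_HYBRID = character(0),
  MH_NO_SPAN1 = "SPAN_1",
  MH_NO_SPAN2 = "SPAN_2",
  MH_NO_SPAN = c("SPAN_1", "SPAN_2"),
  MH_NO_WEIGHT = "WEIGHT",
  MH_NO_THEIGHT = "TASK_HEIGHT"
)

#' Context variables used by a named model variant
#'
#' @param name A hybrid model or ablation-variant name.
#' @return Character vector of included context variables, in encoding order.
#' @export
context_vars_for <- function(name) {
  if (!name %in% names(.excluded_vars)) stop("unknown variant: ", name, call. = FALSE)
  setdiff(c("WEIGHT", "SPAN_1", "SPAN_2", "TASK_HEIGHT"), .excluded_vars[[name]])
}

# Encoded dimension of a context-variable set (task height one-hot spans 3).
.context_dim <- function(vars) {
  sum(ifelse(vars == "TASK_HEIGHT", 3L, 1L))
}

#' Build a named model specification
#'
#' Architectures:
#' \describe{
#'   \item{M_EMG}{EMG branch -> Dense(32 -> 160, ReLU) -> Dense(160 -> 16,
#'     ReLU) -> 2-unit softmax.}
#'   \item{M_CONTEXT}{context branch -> 2-unit softmax.}
#'   \item{M_HYBRID}{both branches, embeddings concatenated (32 + 32 = 64) ->
#'     Dense(64 -> 160, ReLU) -> Dense(160 -> 16, ReLU) -> 2-unit softmax;
#'     23,730 trainable parameters at the full 6-dim context input.}
#' }
#' The ablation variants (`MH_NO_SPAN1`, `MH_NO_SPAN2`, `MH_NO_SPAN`,
#' `MH_NO_WEIGHT`, `MH_NO_THEIGHT`) are `M_HYBRID` with the named context
#' variables excluded at the encoding step; they differ from the full model
#' only in the first context dense layer's parameters.
#'
#' @param name Model name.
#' @param context_input_dim Context vector dimension; defaults to the named
#'   variant's own dimension and is validated against it.
#' @return An object of class `model_spec` with per-section layer lists and
#'   `total_params`.
#' @export
build_model <- function(name, context_input_dim = NULL) {
  hybrid_names <- names(.excluded_vars)
  if (!name %in% c("M_EMG", "M_CONTEXT", hybrid_names)) {
    stop("unknown model name: ", name, call. = FALSE)
  }
  head_from <- function(d_in) list(
    layer_spec("dense", units_or_filters = 160, activation = "relu", in_dim = d_in),
    layer_spec("dense", units_or_filters = 16, activation = "relu", in_dim = 160),
    layer_spec("dense", units_or_filters = 2, activation = "softmax", in_dim = 16)
  )
  if (name == "M_EMG") {
    spec <- list(name = name, context_input_dim = 0L, emg = build_emg_branch(),
                 context = NULL, head = head_from(32))
  } else if (name == "M_CONTEXT") {
    d <- if (is.null(context_input_dim)) 6L else as.integer(context_input_dim)
    spec <- list(name = name, context_input_dim = d, emg = NULL,
                 context = build_context_branch(d),
                 head = list(layer_spec("dense", units_or_filters = 2,
                                        activation = "softmax", in_dim = 32)))
  } else {
    d_expected <- .context_dim(context_vars_for(name))
    d <- if (is.null(context_input_dim)) d_expected else as.integer(context_input_dim)
    if (d != d_expected) {
      stop(sprintf("%s expects context_input_dim %d, got %d", name, d_expected, d),
           call. = FALSE)
    }
    spec <- list(name = name, context_input_dim = d, emg = build_emg_branch(),
                 context = build_context_branch(d),
                 head = c(list(layer_spec("concat")), head_from(64)))
  }
  spec$excluded_variables <- if (name %in% hybrid_names) .excluded_vars[[name]] else NULL
  spec <- structure(spec, class = "model_spec")
  spec$total_params <- count_params(spec)
  spec
}

#' Total trainable parameters of a model spec
#'
#' Sums the closed-form per-layer counts. Equals the instantiated network's
#' own trainable-parameter count (see [nn_param_count()]).
#'
#' @param spec A [build_model()] result (or a bare list of `layer_spec`s).
#' @return Integer parameter count.
#' @export
count_params <- function(spec) {
  layers <- if (inherits(spec, "model_spec")) {
    c(spec$emg, spec$context, spec$head)
  } else {
    spec
  }
  sum(vapply(layers, `[[`, integer(1), "param_count"))
}

#' Serialize a model spec to human-readable text
#'
#' One line per layer (section, kind, dims, activation, parameter count) plus
#' the total, for diffing in tests and reports.
#'
#' @param spec A [build_model()] result.
#' @return Character vector of lines.
#' @export
format_model_spec <- function(spec) {
  fmt_section <- function(layers, section) {
    vapply(layers, function(l) {
      sprintf("%-8s %-20s units=%-4s k=%-3s act=%-8s params=%d",
              section, l$kind,
              ifelse(is.na(l$units_or_filters), "-", l$units_or_filters),
              ifelse(is.na(l$kernel_size), "-", l$kernel_size),
              l$activation, l$param_count)
    }, character(1))
  }
  c(sprintf("model: %s (context_input_dim=%d)", spec$name, spec$context_input_dim),
    if (!is.null(spec$emg)) fmt_section(spec$emg, "emg"),
    if (!is.null(spec$context)) fmt_section(spec$context, "context"),
    fmt_section(spec$head, "head"),
    sprintf("total_params: %d", spec$total_params))
}

#' @export
print.model_spec <- function(x, ...) {
  cat(format_model_spec(x), sep = "\n")
  invisible(x)
}
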