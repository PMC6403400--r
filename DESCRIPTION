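Package: eventdff
Title: Event-Based Depth from Focus with a Spiking Focus-Detection Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates an event camera (dynamic vision sensor) observing a
    scene while a liquid-lens optical system sweeps its focal distance,
    detects the per-pixel time of focus from the polarity inversion of the
    resulting ON/OFF contrast events, and inverts the lens optics to
    recover a metric depth map. Focus detection is available both as a
    compact five-neuron-per-pixel leaky integrate-and-fire spiking circuit
    and as a non-spiking polarity-inversion reference detector. Includes a
    geometric-optics layer (blur-circle size, Gaussian point-spread-function
    width, thin-lens conjugates, hyperfocal distance), a synthetic scene
    renderer and fixture generator, depth-map assembly with error metrics,
    plotting helpers, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    EBImage,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
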