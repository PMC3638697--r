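Package: mrewave
Title: Model-Independent Wave-Image Analysis for Magnetic Resonance
    Elastography
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of two-dimensional complex shear-wave images from
    magnetic resonance elastography (MRE) without fitting a global wave
    model.  At each probe point a Gaussian-windowed Fourier (Gabor)
    transform of the complex displacement field is computed; the location
    of the strongest spectral peak yields the local wave vector of the
    dominant plane-wave component, and a weighted least-squares fit of
    the spectral phase gradient around that peak yields the local
    attenuation vector.  Both are converted to storage and loss moduli
    through the viscoelastic dispersion relation.  Also provides
    strongest-peak spectral denoising filters, a synthetic wave-field
    generator with attenuation and Gaussian noise for end-to-end
    validation, delimited-text and TIFF input/output, quiver and modulus
    figures, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    grDevices,
    jsonlite,
    optparse,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
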