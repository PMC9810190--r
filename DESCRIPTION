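Package: grainGerm
Title: Automated Assessment of Rice Grain Germination Rate from Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Counts rice grains and germinated grains in photographs of
    seeds on a dark background, and reports the germination rate. Grains
    are segmented by two-center k-means clustering on clipped red-minus-blue
    and green-minus-blue color features, then refined by removing dark
    shadow borders below a red-histogram valley threshold located on a
    smoothed, quintic-fitted histogram. Touching grains are counted without
    being separated: the area of each connected region is divided by an
    automatically estimated optimal single-grain area read off the sorted
    area-distribution curve. White germs are detected among non-grain
    pixels by a gray-level threshold, an area window relative to the
    single-grain area, and the ratio of grain-contact length to germ
    perimeter. A seeded synthetic-scene generator with ground truth
    supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, tools, png, jpeg, tiff, EBImage, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
biocViews: Software, CellBasedAssays, Segmentation, Classification
RoxygenNote: 7.3.3
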