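{
  "version": "3.16.7",
  "flags": {},
  "shapes": [
    {"label": "ear", "points": [[12.0, 5.0]], "shape_type": "point"},
    {"label": "ear", "points": [[3.0, 8.0]], "shape_type": "point"},
    {"label": "ear", "points": [[44.0, 17.0]], "shape_type": "point"},
    {"label": "ear", "points": [[27.0, 33.0]], "shape_type": "point"},
    {"label": "ear", "points": [[9.0, 41.0]], "shape_type": "point"},
    {"label": "ear", "points": [[56.0, 2.0]], "shape_type": "point"},
    {"label": "ear", "points": [[31.0, 52.0]], "shape_type": "point"},
    {"label": "ear", "points": [[48.0, 48.0]], "shape_type": "point"},
    {"label": "ear", "points": [[20.0, 20.0]], "shape_type": "point"},
    {"label": "ear", "points": [[61.0, 30.0]], "shape_type": "point"},
    {"label": "ear", "points": [[5.0, 59.0]], "shape_type": "point"},
    {"label": "ear", "points": [[38.0, 11.0]], "shape_type": "point"}
  ],
  "imagePath": "synthetic_quadrat.png",
  "imageHeight": 64,
  "imageWidth": 64
}
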