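{
  "type": "FeatureCollection",
  "comment": "SYNTHETIC stand-in polygons: nine non-overlapping rectangles loosely placed over the real biogeographic regions. The real merged-ecoregion polygons are not redistributable; these are for tests and format illustration only.",
  "features": [
    {"type": "Feature", "properties": {"area": "And", "name": "Andes (synthetic)"},
     "geometry": {"type": "Polygon", "coordinates": [[[-80, -30], [-70, -30], [-70, 10], [-80, 10], [-80, -30]]]}},
    {"type": "Feature", "properties": {"area": "CAm", "name": "Central America/Caribbean (synthetic)"},
     "geometry": {"type": "Polygon", "coordinates": [[[-92, 8], [-60, 8], [-60, 25], [-92, 25], [-92, 8]]]}},
    {"type": "Feature", "properties": {"area": "Pat", "name": "Patagonia (synthetic)"},
     "geometry": {"type": "Polygon", "coordinates": [[[-76, -56], [-64, -56], [-64, -40], [-76, -40], [-76, -56]]]}},
    {"type": "Feature", "properties": {"area": "TSA", "name": "Tropical South America (synthetic)"},
     "geometry": {"type": "Polygon", "coordinates": [[[-69.5, -20], [-35, -20], [-35, 7], [-69.5, 7], [-69.5, -20]]]}},
    {"type": "Feature", "properties": {"area": "Afr", "name": "Afrotropics (synthetic)"},
     "geometry": {"type": "Polygon", "coordinates": [[[-20, -35], [50, -35], [50, 12], [-20, 12], [-20, -35]]]}},
    {"type": "Feature", "properties": {"area": "Aus", "name": "Australasia and Oceania (synthetic)"},
     "geometry": {"type": "Polygon", "coordinates": [[[110, -50], [180, -50], [180, -12], [110, -12], [110, -50]]]}},
    {"type": "Feature", "properties": {"area": "Ind", "name": "Indomalaya (synthetic)"},
     "geometry": {"type": "Polygon", "coordinates": [[[60, -10], [110, -10], [110, 28], [60, 28], [60, -10]]]}},
    {"type": "Feature", "properties": {"area": "Nea", "name": "Nearctic (synthetic)"},
     "geometry": {"type": "Polygon", "coordinates": [[[-170, 26], [-50, 26], [-50, 75], [-170, 75], [-170, 26]]]}},
    {"type": "Feature", "properties": {"area": "Pal", "name": "Palaearctic (synthetic)"},
     "geometry": {"type": "Polygon", "coordinates": [[[-15, 30], [180, 30], [180, 78], [-15, 78], [-15, 30]]]}}
  ]
}
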