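{
  "type": "FeatureCollection",
  "features": [
    {
      "type": "Feature",
      "properties": {"id": "park_east", "city_id": "alpha"},
      "geometry": {
        "type": "Polygon",
        "coordinates": [[[1200, 1200], [1700, 1200], [1700, 1700], [1200, 1700], [1200, 1200]]]
      }
    },
    {
      "type": "Feature",
      "properties": {"id": "park_hill", "city_id": "alpha"},
      "geometry": {
        "type": "Polygon",
        "coordinates": [[[2800, 2300], [3400, 2300], [3400, 2700], [2800, 2700], [2800, 2300]]]
      }
    },
    {
      "type": "Feature",
      "properties": {"id": "riverside", "city_id": "alpha", "area_ha": 14.96},
      "geometry": {"type": "Point", "coordinates": [5000, 4300]}
    },
    {
      "type": "Feature",
      "properties": {"id": "pocket", "city_id": "alpha"},
      "geometry": {
        "type": "Polygon",
        "coordinates": [[[900, 6300], [990, 6300], [990, 6390], [900, 6390], [900, 6300]]]
      }
    },
    {
      "type": "Feature",
      "properties": {"id": "central_green", "city_id": "beta", "area_m2": 60000},
      "geometry": {"type": "Point", "coordinates": [1800, 1800]}
    }
  ]
}
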