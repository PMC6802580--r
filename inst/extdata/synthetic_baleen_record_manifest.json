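{"kind":"migratory_profile","synthetic":true,"seed":424242,"truth":{"hypothesis":"migratory","kind":"MIGRATORY","nDays":2625,"growthRate":13.5,"anchorDate":"1891-03-01","noiseSd":0.1,"start":{"lat":21.7001408152,"lon":-34.2724469258}},"version":"0.1.0"}
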