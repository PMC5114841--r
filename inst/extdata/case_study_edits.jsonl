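{"kind":"split","targets":["quantity of carapace"],"components":["length","width"]}
{"kind":"split","targets":["quantity of abdomen"],"components":["length","width"]}
{"kind":"split","targets":["quantity of sternum"],"components":["length","width"]}
{"kind":"split","targets":["quantity of prosoma"],"components":["length","width"]}
{"kind":"split","targets":["quantity of ocular-area"],"components":["length","width"]}
{"kind":"split","targets":["quantity of opisthosomum"],"components":["length","width"]}
{"kind":"split","targets":["quantity of ii"],"components":["tibia","metatarsus"]}
{"kind":"split","targets":["quantity of iv"],"components":["tibia","metatarsus"]}
{"kind":"delete","targets":["quantity of leg"]}
{"kind":"delete","targets":["character of carapace"]}
{"kind":"delete","targets":["length of carapace"]}
{"kind":"delete","targets":["width of carapace"]}
{"kind":"delete","targets":["length of abdomen"]}
{"kind":"delete","targets":["length of sternum"]}
{"kind":"delete","targets":["quantity of iii tibia/metatarsu"]}
{"kind":"delete","targets":["quantity of iii"]}
{"kind":"delete","targets":["quantity of leg-3"]}
{"kind":"rename","targets":["quantity of whole-organism"],"dest":"length of whole-organism (new)"}
{"kind":"rename","targets":["quantity of carapace (split, length)"],"dest":"length of carapace (new)"}
{"kind":"rename","targets":["quantity of carapace (split, width)"],"dest":"width of carapace (new)"}
{"kind":"rename","targets":["quantity of abdomen (split, length)"],"dest":"length of abdomen (new)"}
{"kind":"rename","targets":["quantity of sternum (split, length)"],"dest":"length of sternum (new)"}
{"kind":"rename","targets":["quantity of spiracle-epigastrium"],"dest":"distance of spiracle-epigastrium (new)"}
{"kind":"rename","targets":["quantity of spiracle-spinneret"],"dest":"distance of spiracle-spinneret (new)"}
{"kind":"rename","targets":["quantity of i tibia"],"dest":"length of leg i tibia (new)"}
{"kind":"rename","targets":["quantity of i metatarsus"],"dest":"length of leg i metatarsus (new)"}
{"kind":"rename","targets":["quantity of ii tibia"],"dest":"length of leg ii tibia (new)"}
{"kind":"rename","targets":["quantity of ii metatarsus"],"dest":"length of leg ii metatarsus (new)"}
{"kind":"rename","targets":["quantity of iii tibia"],"dest":"length of leg iii tibia (new)"}
{"kind":"rename","targets":["quantity of iii metatarsus"],"dest":"length of leg iii metatarsus (new)"}
{"kind":"rename","targets":["quantity of iv tibia"],"dest":"length of leg iv tibia (new)"}
{"kind":"rename","targets":["quantity of iv metatarsus"],"dest":"length of leg iv metatarsus (new)"}
{"kind":"merge","targets":["length of whole-organism (new)","quantity of body"],"dest":"length of whole-organism (new)"}
{"kind":"merge","targets":["length of carapace (new)","quantity of prosoma (split, length)","quantity of thoracic-groove","quantity of cephalic-area","quantity of front","quantity of ocular-area (split, length)"],"dest":"length of carapace (new)"}
{"kind":"merge","targets":["width of carapace (new)","quantity of prosoma (split, width)","quantity of ocular-area (split, width)"],"dest":"width of carapace (new)"}
{"kind":"merge","targets":["length of palpal-tarsus","quantity of palpal-tarsus"],"dest":"length of palpal-tarsus"}
{"kind":"merge","targets":["length of abdomen (new)","quantity of opisthosomum (split, length)"],"dest":"length of abdomen (new)"}
{"kind":"merge","targets":["width of abdomen","quantity of opisthosomum (split, width)","quantity of abdomen (split, width)"],"dest":"width of abdomen"}
{"kind":"merge","targets":["quantity of sternum (split, width)","width of sternum"],"dest":"width of sternum"}
{"kind":"merge","targets":["distance of spiracle-spinneret (new)","quantity of spiracle","quantity of spiracle spinneret"],"dest":"distance of spinneret-spiracle (new)"}
{"kind":"merge","targets":["quantity of epigastric-furrow","distance of spiracle-epigastrium (new)","quantity of epigastrium-epigastrium","quantity of epigastrium-spiracle"],"dest":"distance of epigastrium-spiracle (new)"}
{"kind":"merge","targets":["length of leg ii tibia (new)","quantity of ii (split, tibia)"],"dest":"length of leg ii tibia (new)"}
{"kind":"merge","targets":["length of leg ii metatarsus (new)","quantity of ii (split, metatarsus)"],"dest":"length of leg ii metatarsus (new)"}
{"kind":"merge","targets":["length of leg iv tibia (new)","quantity of iv (split, tibia)"],"dest":"length of leg iv tibia (new)"}
{"kind":"merge","targets":["length of leg iv metatarsus (new)","quantity of iv (split, metatarsus)"],"dest":"length of leg iv metatarsus (new)"}
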