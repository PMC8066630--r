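species	genus	family
Dicentrarchus labrax	Dicentrarchus	Moronidae
Sparus aurata	Sparus	Sparidae
Thunnus thynnus	Thunnus	Scombridae
Thunnus albacares	Thunnus	Scombridae
Thunnus obesus	Thunnus	Scombridae
Thunnus orientalis	Thunnus	Scombridae
Hirundichthys affinis	Hirundichthys	Exocoetidae
Hirundichthys oxycephalus	Hirundichthys	Exocoetidae
Hirundichthys coromandelensis	Hirundichthys	Exocoetidae
Cheilopogon atrisignis	Cheilopogon	Exocoetidae
Seriola lalandi	Seriola	Carangidae
Xiphias gladius	Xiphias	Xiphiidae
Mallotus villosus	Mallotus	Osmeridae
Pomatomus saltatrix	Pomatomus	Pomatomidae
Cyclopterus lumpus	Cyclopterus	Cyclopteridae
Oncorhynchus keta	Oncorhynchus	Salmonidae
Anguilla rostrata	Anguilla	Anguillidae
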