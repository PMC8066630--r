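trade_name	rank	taxon	listed	source	notes
tuna	species	Thunnus thynnus	TRUE	MD n.19105 22/09/2017	name reserved for red tuna
red tuna	species	Thunnus thynnus	TRUE	MD n.19105 22/09/2017	
maguro	species	Thunnus thynnus	TRUE	sushi trade alias of red tuna	
yellowfin tuna	species	Thunnus albacares	TRUE	MD n.19105 22/09/2017	
bigeye tuna	species	Thunnus obesus	TRUE	MD n.19105 22/09/2017	
orientalis tuna	species	Thunnus orientalis	TRUE	MD n.19105 22/09/2017	
oceanic tuna	species	Thunnus orientalis	TRUE	MD n.19105 22/09/2017	
sea bream	species	Sparus aurata	TRUE	MD n.19105 22/09/2017	
common bass	species	Dicentrarchus labrax	TRUE	MD n.19105 22/09/2017	
tobiko	genus	Hirundichthys	FALSE	sushi trade name for flying-fish roe	flying-fish species not in the MD list
tobiko	genus	Cheilopogon	FALSE	sushi trade name for flying-fish roe	flying-fish species not in the MD list
flying fish egg	genus	Hirundichthys	FALSE	menu synonym of tobiko	
flying fish egg	genus	Cheilopogon	FALSE	menu synonym of tobiko	
ikura	genus	Oncorhynchus	TRUE	sushi trade name for salmon roe	
salmon eggs	genus	Oncorhynchus	TRUE	menu synonym of ikura	
lumpfish roe	species	Cyclopterus lumpus	TRUE	MD n.19105 22/09/2017	
anago	genus	Anguilla	TRUE	sushi trade name for eel	
kajiki	species	Xiphias gladius	TRUE	sushi trade name for swordfish	
swordfish	species	Xiphias gladius	TRUE	MD n.19105 22/09/2017	
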