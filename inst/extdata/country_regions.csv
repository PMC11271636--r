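country,region
Algeria,Northern Africa
Egypt,Northern Africa
Libya,Northern Africa
Morocco,Northern Africa
Sudan,Northern Africa
Tunisia,Northern Africa
Angola,Sub-Saharan Africa
Cameroon,Sub-Saharan Africa
Ghana,Sub-Saharan Africa
Kenya,Sub-Saharan Africa
Madagascar,Sub-Saharan Africa
Mauritius,Sub-Saharan Africa
Mozambique,Sub-Saharan Africa
Namibia,Sub-Saharan Africa
Nigeria,Sub-Saharan Africa
Senegal,Sub-Saharan Africa
South Africa,Sub-Saharan Africa
Tanzania,Sub-Saharan Africa
Canada,Northern America
United States,Northern America
Argentina,Latin America & Caribbean
Bahamas,Latin America & Caribbean
Brazil,Latin America & Caribbean
Chile,Latin America & Caribbean
Colombia,Latin America & Caribbean
Cuba,Latin America & Caribbean
Dominican Republic,Latin America & Caribbean
Ecuador,Latin America & Caribbean
Jamaica,Latin America & Caribbean
Mexico,Latin America & Caribbean
Panama,Latin America & Caribbean
Peru,Latin America & Caribbean
Trinidad and Tobago,Latin America & Caribbean
Uruguay,Latin America & Caribbean
Venezuela,Latin America & Caribbean
Kazakhstan,Central Asia
Turkmenistan,Central Asia
Uzbekistan,Central Asia
China,Eastern Asia
Hong Kong,Eastern Asia
Japan,Eastern Asia
North Korea,Eastern Asia
South Korea,Eastern Asia
Taiwan,Eastern Asia
Brunei,South-eastern Asia
Cambodia,South-eastern Asia
Indonesia,South-eastern Asia
Malaysia,South-eastern Asia
Myanmar,South-eastern Asia
Philippines,South-eastern Asia
Singapore,South-eastern Asia
Thailand,South-eastern Asia
Vietnam,South-eastern Asia
Bangladesh,Southern Asia
India,Southern Asia
Iran,Southern Asia
Maldives,Southern Asia
Pakistan,Southern Asia
Sri Lanka,Southern Asia
Bahrain,Western Asia
Cyprus,Western Asia
Georgia,Western Asia
Iraq,Western Asia
Israel,Western Asia
Jordan,Western Asia
Kuwait,Western Asia
Lebanon,Western Asia
Oman,Western Asia
Qatar,Western Asia
Saudi Arabia,Western Asia
Turkey,Western Asia
United Arab Emirates,Western Asia
Yemen,Western Asia
Bulgaria,Eastern Europe
Poland,Eastern Europe
Romania,Eastern Europe
Russia,Eastern Europe
Ukraine,Eastern Europe
Denmark,Northern Europe
Estonia,Northern Europe
Finland,Northern Europe
Iceland,Northern Europe
Ireland,Northern Europe
Latvia,Northern Europe
Lithuania,Northern Europe
Norway,Northern Europe
Sweden,Northern Europe
United Kingdom,Northern Europe
Albania,Southern Europe
Croatia,Southern Europe
Gibraltar,Southern Europe
Greece,Southern Europe
Italy,Southern Europe
Malta,Southern Europe
Montenegro,Southern Europe
Portugal,Southern Europe
Slovenia,Southern Europe
Spain,Southern Europe
Belgium,Western Europe
France,Western Europe
Germany,Western Europe
Netherlands,Western Europe
Australia,Australia & New Zealand
New Zealand,Australia & New Zealand
Fiji,Melanesia
New Caledonia,Melanesia
Papua New Guinea,Melanesia
Solomon Islands,Melanesia
Vanuatu,Melanesia
Guam,Micronesia
Kiribati,Micronesia
Marshall Islands,Micronesia
Micronesia,Micronesia
Nauru,Micronesia
Palau,Micronesia
French Polynesia,Polynesia
Samoa,Polynesia
Tonga,Polynesia
Tuvalu,Polynesia
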